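write_fasta <- function(seqs, path) {
  writeLines(unlist(purrr::imap(seqs, ~ c(paste0(">", .y), .x))), path)
}

write_site_tsv <- function(rows, path) {
  writeLines(c("seq_id\tcenter\tsubtype\tlabel", rows), path)
}

test_that("site reading drops overruns and duplicates, keeps valid rows", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "x.fasta")
  tsv <- file.path(dir, "x.tsv")
  set.seed(8)
  write_fasta(list(s1 = random_rna(60), s2 = random_rna(40)), fa)

  write_site_tsv("s1\t30\tAm\t1", tsv)
  expect_equal(nrow(read_sites(fa, tsv)), 1)

  write_site_tsv("s2\t10\tCm\t1", tsv)  # left flank overruns at flank 25
  expect_message(out <- read_sites(fa, tsv), "1 site record")
  expect_equal(nrow(out), 0)
  expect_equal(attr(out, "n_dropped"), 1)

  write_site_tsv(c("s1\t30\tUm\t1", "s1\t30\tUm\t1"), tsv)  # duplicate
  expect_message(out <- read_sites(fa, tsv), "1 duplicate")
  expect_equal(nrow(out), 1)
})

test_that("site reading fails loudly on bad ids and malformed rows", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "x.fasta")
  tsv <- file.path(dir, "x.tsv")
  set.seed(9)
  write_fasta(list(s1 = random_rna(60)), fa)
  write_site_tsv("nope\t30\tAm\t1", tsv)
  expect_error(read_sites(fa, tsv), "nope")
  write_site_tsv(c("s1\t30\tAm\t1", "s1\tfoo\tAm\t1"), tsv)
  expect_error(read_sites(fa, tsv), "line 3")
  write_site_tsv("s1\t30\tXm\t1", tsv)
  expect_error(read_sites(fa, tsv), "malformed")
})

test_that("one-based site tables are shifted onto the internal convention", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "x.fasta")
  tsv <- file.path(dir, "x.tsv")
  seq <- paste0(strrep("C", 25), "A", strrep("G", 25))  # A at 0-based 25
  write_fasta(list(s1 = seq), fa)
  write_site_tsv("s1\t26\tAm\t1", tsv)
  sites <- read_sites(fa, tsv, one_based = TRUE)
  expect_equal(sites$center, 25L)
  w <- build_windows(sites, fa)
  expect_equal(substr(w$bases, 26, 26), "A")
})

test_that("window extraction is center-anchored and transcribes T to U", {
  set.seed(10)
  parent <- random_rna(51)
  expect_equal(extract_window(parent, 25, 25), parent)
  expect_equal(extract_window("AAACA", 2, 2), "AAACA")
  expect_equal(extract_window("AATCA", 2, 2), "AAUCA")
  expect_error(extract_window("AAACA", 1, 2), "overruns")
  expect_error(extract_window("AAXCA", 2, 2), "illegal base")
})

test_that("windows round-trip: the center base is preserved and counts conserved", {
  dir <- withr::local_tempdir()
  set.seed(12)
  n <- 12
  seqs <- setNames(as.list(replicate(n, random_rna(80))), paste0("s", 1:n))
  centers <- sample(25:54, n, replace = TRUE)
  # force the subtype base at each center so records are coherent
  subs <- sample(c("Am", "Cm", "Gm", "Um"), n, replace = TRUE)
  for (i in 1:n) {
    substr(seqs[[i]], centers[i] + 1, centers[i] + 1) <- substr(subs[i], 1, 1)
  }
  fa <- file.path(dir, "x.fasta"); tsv <- file.path(dir, "x.tsv")
  write_fasta(seqs, fa)
  write_site_tsv(sprintf("s%d\t%d\t%s\t%d", 1:n, centers, subs,
                         rep_len(c(1, 0), n)), tsv)
  sites <- read_sites(fa, tsv)
  expect_equal(nrow(sites) + attr(sites, "n_dropped"), n)
  w <- build_windows(sites, fa)
  expect_equal(nrow(w), nrow(sites))
  for (i in seq_len(nrow(w))) {
    expect_equal(substr(w$bases[i], 26, 26),
                 substr(seqs[[w$seq_id[i]]], w$center[i] + 1, w$center[i] + 1))
  }
})

test_that("record invariants are enforced at window construction", {
  seqs <- c(s1 = paste0(strrep("C", 25), "A", strrep("G", 25)))
  sites <- tibble::tibble(seq_id = "s1", center = 25L, subtype = "Am",
                          label = 1L)
  expect_equal(nrow(build_windows(sites, seqs)), 1)
  # positive whose center base contradicts its subtype
  sites$subtype <- "Um"
  expect_error(build_windows(sites, seqs), "center base A but subtype Um")
  # negatives may carry any center base
  sites$label <- 0L
  expect_equal(nrow(build_windows(sites, seqs)), 1)
  # N at the candidate position is rejected outright
  seqs_n <- c(s1 = paste0(strrep("C", 25), "N", strrep("G", 25)))
  expect_error(build_windows(sites, seqs_n), "N at the candidate")
})

test_that("structure attachment validates length and balance", {
  w <- tibble::tibble(bases = c("AAAAA", "GGGGG"), label = c(1, 0),
                      dotbracket = NA_character_)
  dir <- withr::local_tempdir()
  db <- file.path(dir, "s.db")
  writeLines(c("(...)", "....."), db)
  out <- attach_structures(w, dotbracket_path = db)
  expect_equal(out$dotbracket, c("(...)", "....."))

  writeLines(c("((..)", "....."), db)
  expect_error(attach_structures(w, dotbracket_path = db),
               "window 1.*unbalanced")
  writeLines("(...)", db)
  expect_error(attach_structures(w, dotbracket_path = db), "1 structures")
  expect_error(attach_structures(w, hook = function(b) "...."),
               "window 1: structure length 4")
  expect_error(attach_structures(w), "exactly one")
  # a well-behaved hook is applied per window
  out <- attach_structures(w, hook = function(b) strrep(".", nchar(b)))
  expect_equal(out$dotbracket, c(".....", "....."))
})

test_that("the RNAfold hook returns a parseable same-length structure", {
  hook <- rnafold_hook()
  s <- "GGGGGAAAACCCCC"
  db <- hook(s)
  expect_equal(nchar(db), nchar(s))
  expect_silent(parse_dotbracket(db))
  expect_gt(nrow(parse_dotbracket(db)), 0)  # strong stem must pair
})
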