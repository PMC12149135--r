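IUPAC <- list(A = "A", C = "C", G = "G", U = "U",
              R = c("A", "G"), Y = c("C", "U"), S = c("C", "G"),
              W = c("A", "U"), K = c("G", "U"), M = c("A", "C"),
              B = c("C", "G", "U"), D = c("A", "G", "U"),
              H = c("A", "C", "U"), V = c("A", "C", "G"),
              N = c("A", "C", "G", "U"))

RNA_COMPLEMENT <- c(A = "U", U = "A", G = "C", C = "G")

#' Simulate an Nm-like benchmark dataset
#'
#' Generates balanced positive/negative fixed-length windows with
#' controllable class signal in each feature view, so every stage of the
#' pipeline is testable without experimental data.
#'
#' Background bases are i.i.d. uniform over A/C/G/U. Every window —
#' positive or negative — carries its subtype's nucleotide (A for Am,
#' C for Cm, ...) at the center, making the negatives *hard*: the center
#' base alone carries no class signal. Subtypes are drawn from
#' `subtype_props`, whose defaults are the observed composition of
#' experimentally mapped human Nm sites (Am 22.1%, Cm 26.1%, Gm 20.5%,
#' Um 31.3%). Positives receive, independently with probability
#' `motif_strength`, a degenerate IUPAC `motif` written at 0-based
#' offset `motif_pos` (`N` motif letters leave the background base; the
#' center base is re-asserted afterwards, since the subtype invariant is
#' hard). With probability `struct_signal`, a positive additionally gets
#' an 8-bp complementary stem planted around the center so the window
#' folds into a hairpin enclosing it. Structures for all windows come
#' from the deterministic maximum-pairing folder [fold_nussinov()].
#'
#' @param n_per_class windows per class (default 1000)
#' @param window_len odd window length (default 51)
#' @param subtype_props named proportions over Am/Cm/Gm/Um (must sum
#'   to 1)
#' @param motif IUPAC motif planted in positives (default `"GGNCU"`)
#' @param motif_pos 0-based offset of the motif in the window (default
#'   23, i.e. straddling the center of a 51-nt window)
#' @param motif_strength probability a positive carries the motif
#' @param struct_signal probability a positive carries the hairpin stem
#' @param seed RNG seed; generation is fully deterministic given it
#' @return A windows tibble (`seq_id`, `center`, `subtype`, `label`,
#'   `bases`, `dotbracket`) ready for [encode_windows()].
#' @export
simulate_nm <- function(n_per_class = 1000, window_len = 51,
                        subtype_props = c(Am = 0.221, Cm = 0.261,
                                          Gm = 0.205, Um = 0.313),
                        motif = "GGNCU", motif_pos = 23,
                        motif_strength = 0.9, struct_signal = 0,
                        seed = 1) {
  stopifnot(window_len %% 2 == 1, n_per_class >= 1)
  if (abs(sum(subtype_props) - 1) > 1e-9) {
    stop("subtype_props must sum to 1", call. = FALSE)
  }
  if (!setequal(names(subtype_props), NM_SUBTYPES)) {
    stop("subtype_props must be named Am/Cm/Gm/Um", call. = FALSE)
  }
  motif_chars <- strsplit(motif, "")[[1]]
  if (motif_pos < 0 || motif_pos + length(motif_chars) > window_len) {
    stop("motif overruns the window", call. = FALSE)
  }
  if (!all(motif_chars %in% names(IUPAC))) {
    stop("motif must be IUPAC letters", call. = FALSE)
  }
  L <- window_len
  center <- (L - 1L) %/% 2L  # 0-based
  stem <- 8L
  if (struct_signal > 0 && (center - 17 < 0 || center + 17 >= L)) {
    stop("window too short for the planted stem", call. = FALSE)
  }
  set.seed(seed)
  n <- 2L * n_per_class
  subtype <- sample(NM_SUBTYPES, n, replace = TRUE,
                    prob = subtype_props[NM_SUBTYPES])
  label <- rep(c(1L, 0L), each = n_per_class)
  bases <- character(n)
  for (s in seq_len(n)) {
    w <- sample(RNA_BASES, L, replace = TRUE)
    if (label[s] == 1L) {
      if (stats::runif(1) < motif_strength) {
        for (m in seq_along(motif_chars)) {
          if (motif_chars[m] != "N") {
            pool <- IUPAC[[motif_chars[m]]]
            w[motif_pos + m] <- if (length(pool) == 1) pool
                                else sample(pool, 1)
          }
        }
      }
      if (stats::runif(1) < struct_signal) {
        left <- (center - 17):(center - 10) + 1L   # 1-based
        right <- (center + 10):(center + 17) + 1L
        w[right] <- rev(unname(RNA_COMPLEMENT[w[left]]))
      }
    }
    w[center + 1L] <- subtype_base(subtype[s])
    bases[s] <- paste(w, collapse = "")
  }
  db <- vapply(bases, fold_nussinov, character(1), USE.NAMES = FALSE)
  tibble::tibble(
    seq_id = sprintf("synth_%05d", seq_len(n)),
    center = center, subtype = subtype, label = label,
    bases = bases, dotbracket = db
  )
}

#' Write a simulated dataset as on-disk fixtures
#'
#' Writes the three files the readers consume: a FASTA of the windows
#' (each window its own record), a TSV site table (`seq_id`, `center`,
#' `subtype`, `label`; 0-based centers), and a dot-bracket file with one
#' structure line per window, in window order. The files round-trip
#' losslessly through [read_sites()], [build_windows()] and
#' [attach_structures()].
#'
#' @param samples windows tibble (e.g. from [simulate_nm()])
#' @param out_dir output directory (created if needed)
#' @return Invisibly, the three file paths.
#' @export
write_fixture <- function(samples, out_dir) {
  stopifnot(nrow(samples) > 0)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(out_dir, "windows.fasta")
  tsv <- file.path(out_dir, "sites.tsv")
  db <- file.path(out_dir, "structures.db")
  ss <- Biostrings::BStringSet(samples$bases)
  names(ss) <- samples$seq_id
  Biostrings::writeXStringSet(ss, fasta)
  utils::write.table(
    samples[, c("seq_id", "center", "subtype", "label")], tsv,
    sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(samples$dotbracket, db)
  invisible(c(fasta = fasta, sites = tsv, structures = db))
}

#' Read a fixture directory back into a windows tibble
#' @param dir directory written by [write_fixture()]
#' @param flank flank length (default 25)
#' @return windows tibble
#' @export
read_fixture <- function(dir, flank = 25) {
  sites <- read_sites(file.path(dir, "windows.fasta"),
                      file.path(dir, "sites.tsv"), flank = flank)
  w <- build_windows(sites, file.path(dir, "windows.fasta"), flank = flank)
  attach_structures(w, dotbracket_path = file.path(dir, "structures.db"))
}
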