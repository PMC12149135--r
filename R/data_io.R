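NM_SUBTYPES <- c("Am", "Cm", "Gm", "Um")

subtype_base <- function(subtype) {
  substr(subtype, 1, 1)
}

#' Read candidate Nm sites from a FASTA and a site table
#'
#' The site table is a tab-separated file with a header and columns
#' `seq_id`, `center`, `subtype`, `label`. `center` is the 0-based
#' position of the candidate nucleotide on its parent sequence (pass
#' `one_based = TRUE` for 1-based tables); `subtype` is one of Am, Cm,
#' Gm, Um; `label` is 1 (methylated) or 0. Records whose `flank`-nt
#' window would overrun either end of the parent sequence are dropped
#' with a message; duplicate `(seq_id, center)` records keep the first.
#'
#' @param fasta_path FASTA of parent sequences (DNA `T` is tolerated and
#'   transcribed to `U` on window extraction).
#' @param site_table_path TSV site table described above.
#' @param flank Flank length used for the overrun check (default 25,
#'   giving 51-nt windows).
#' @param one_based Set `TRUE` if the table's `center` column is 1-based.
#' @return A tibble of site records: `seq_id`, `center`, `subtype`,
#'   `label`, with the number of dropped records in attribute
#'   `n_dropped`.
#' @export
read_sites <- function(fasta_path, site_table_path, flank = 25,
                       one_based = FALSE) {
  seqs <- read_parent_fasta(fasta_path)
  tab <- utils::read.delim(site_table_path, header = TRUE, sep = "\t",
                           colClasses = "character", strip.white = TRUE)
  need <- c("seq_id", "center", "subtype", "label")
  if (!all(need %in% names(tab))) {
    stop("site table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  center <- suppressWarnings(as.integer(tab$center))
  label <- suppressWarnings(as.integer(tab$label))
  bad <- which(is.na(center) | is.na(label) | !label %in% c(0L, 1L) |
                 !tab$subtype %in% NM_SUBTYPES)
  if (length(bad) > 0) {
    stop("malformed site-table row at line ", bad[1] + 1L,
         " (file line incl. header)", call. = FALSE)
  }
  if (one_based) center <- center - 1L
  missing_ids <- setdiff(unique(tab$seq_id), names(seqs))
  if (length(missing_ids) > 0) {
    stop("seq_id not in FASTA: ", paste(missing_ids, collapse = ", "),
         call. = FALSE)
  }
  sites <- tibble::tibble(seq_id = tab$seq_id, center = center,
                          subtype = tab$subtype, label = label)
  dup <- duplicated(sites[, c("seq_id", "center")])
  sites <- sites[!dup, ]
  len <- nchar(seqs)[sites$seq_id]
  keep <- sites$center - flank >= 0 & sites$center + flank < len
  n_dropped <- sum(!keep) + sum(dup)
  if (n_dropped > 0) {
    message(n_dropped, " site record(s) dropped (",
            sum(!keep), " window overrun, ", sum(dup), " duplicate)")
  }
  out <- sites[keep, ]
  attr(out, "n_dropped") <- n_dropped
  out
}

read_parent_fasta <- function(fasta_path) {
  ss <- Biostrings::readBStringSet(fasta_path)
  seqs <- toupper(as.character(ss))
  # keep only the first word of each FASTA header as the id
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Extract one fixed-length window around a site
#'
#' Returns the subsequence `[center - flank, center + flank]`
#' (0-based, inclusive) with DNA `T` transcribed to `U`.
#'
#' @param parent_sequence Parent sequence string.
#' @param center 0-based candidate position.
#' @param flank Bases on each side (default 25 -> 51-nt window).
#' @return Window string of length `2 * flank + 1`.
#' @export
extract_window <- function(parent_sequence, center, flank = 25) {
  stopifnot(flank >= 1)
  L <- nchar(parent_sequence)
  if (center - flank < 0 || center + flank >= L) {
    stop("window [", center - flank, ", ", center + flank,
         "] overruns sequence of length ", L, call. = FALSE)
  }
  w <- substr(parent_sequence, center - flank + 1L, center + flank + 1L)
  w <- chartr("Tt", "Uu", toupper(w))
  check_alphabet(w)
  w
}

#' Build windows for a site table
#'
#' Vectorised [extract_window()] over a sites tibble; the center base of
#' every returned window is the parent base at `center`. Record
#' invariants are enforced here: the candidate position may not be `N`
#' (flanking `N`s are tolerated and encode to zero rows), and a
#' positive record's center base must equal its subtype's nucleotide.
#'
#' @param sites Tibble from [read_sites()] (or compatible).
#' @param fasta_path_or_seqs FASTA path, or a named character vector of
#'   parent sequences.
#' @param flank Flank length (default 25).
#' @return Tibble: `seq_id`, `center`, `subtype`, `label`, `bases`,
#'   `dotbracket` (NA until [attach_structures()]).
#' @export
build_windows <- function(sites, fasta_path_or_seqs, flank = 25) {
  seqs <- if (is.character(fasta_path_or_seqs) &&
                length(fasta_path_or_seqs) == 1 &&
                file.exists(fasta_path_or_seqs)) {
    read_parent_fasta(fasta_path_or_seqs)
  } else fasta_path_or_seqs
  bases <- purrr::map2_chr(sites$seq_id, sites$center,
                           ~ extract_window(seqs[[.x]], .y, flank))
  center_base <- substr(bases, flank + 1L, flank + 1L)
  if (any(center_base == "N")) {
    bad <- which(center_base == "N")[1]
    stop("record ", sites$seq_id[bad], ":", sites$center[bad],
         " has N at the candidate position", call. = FALSE)
  }
  pos_bad <- sites$label == 1 & center_base != subtype_base(sites$subtype)
  if (any(pos_bad)) {
    bad <- which(pos_bad)[1]
    stop("positive record ", sites$seq_id[bad], ":", sites$center[bad],
         " has center base ", center_base[bad], " but subtype ",
         sites$subtype[bad], call. = FALSE)
  }
  dplyr::mutate(tibble::as_tibble(sites), bases = bases,
                dotbracket = NA_character_)
}

#' Attach secondary structures to windows
#'
#' Structures come either from a plain-text dot-bracket file (one line
#' per window, in window order) or from a folding hook: a function
#' mapping a window's bases to a dot-bracket string of the same length.
#' Every structure is validated (length, balanced brackets) before it is
#' attached.
#'
#' @param windows Windows tibble (needs a `bases` column).
#' @param dotbracket_path Path to a dot-bracket file, one line per
#'   window.
#' @param hook A function `function(bases) -> dotbracket`, e.g.
#'   [fold_nussinov] or [rnafold_hook()]. Exactly one of
#'   `dotbracket_path`/`hook` must be given.
#' @return The windows tibble with `dotbracket` filled in.
#' @export
attach_structures <- function(windows, dotbracket_path = NULL, hook = NULL) {
  if (is.null(dotbracket_path) == is.null(hook)) {
    stop("give exactly one of dotbracket_path or hook", call. = FALSE)
  }
  if (!is.null(dotbracket_path)) {
    db <- readLines(dotbracket_path)
    db <- db[nzchar(trimws(db))]
    if (length(db) != nrow(windows)) {
      stop("dot-bracket file has ", length(db), " structures for ",
           nrow(windows), " windows", call. = FALSE)
    }
  } else {
    db <- vapply(windows$bases, hook, character(1), USE.NAMES = FALSE)
  }
  for (s in seq_len(nrow(windows))) {
    if (nchar(db[s]) != nchar(windows$bases[s])) {
      stop("window ", s, ": structure length ", nchar(db[s]),
           " != window length ", nchar(windows$bases[s]), call. = FALSE)
    }
    ok <- tryCatch({ parse_dotbracket(db[s]); TRUE },
                   error = function(e) conditionMessage(e))
    if (!isTRUE(ok)) stop("window ", s, ": ", ok, call. = FALSE)
  }
  dplyr::mutate(windows, dotbracket = db)
}

#' Folding hook that shells out to RNAfold
#'
#' Returns a hook for [attach_structures()] that runs ViennaRNA's
#' `RNAfold --noPS` on each window and parses the dot-bracket from its
#' second output line. Requires the `RNAfold` binary on the PATH.
#'
#' @param rnafold RNAfold executable name/path.
#' @return A function `function(bases) -> dotbracket`.
#' @export
rnafold_hook <- function(rnafold = "RNAfold") {
  if (Sys.which(rnafold) == "") {
    stop("RNAfold binary not found on PATH", call. = FALSE)
  }
  function(bases) {
    out <- system2(rnafold, args = "--noPS", input = bases, stdout = TRUE)
    if (length(out) < 2) stop("RNAfold produced no structure", call. = FALSE)
    # second line: dot-bracket followed by " (energy)"
    db <- sub("\\s+\\(.*\\)\\s*$", "", out[2])
    db
  }
}
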