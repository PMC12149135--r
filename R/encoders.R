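#' @useDynLib nmview, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

RNA_BASES <- c("A", "C", "G", "U")

check_alphabet <- function(bases, allow_n = TRUE) {
  chars <- strsplit(bases, "")[[1]]
  allowed <- c(RNA_BASES, if (allow_n) "N")
  bad <- setdiff(unique(chars), allowed)
  if (length(bad) > 0) {
    stop("illegal base(s) in sequence: ", paste(bad, collapse = ", "),
         " (alphabet is A/C/G/U", if (allow_n) "/N", ")", call. = FALSE)
  }
  chars
}

#' One-hot encode an RNA window
#'
#' Each base maps to a 4-bit indicator row in the fixed column order
#' A, C, G, U. `N` encodes to an all-zero row, so ambiguous bases carry
#' no sequence signal.
#'
#' @param bases A single string over `A`/`C`/`G`/`U`/`N` (T is not
#'   accepted here; windows are transcribed at extraction time).
#' @return An `L x 4` binary matrix with `colnames` A, C, G, U.
#' @examples
#' encode_onehot("AACUG")
#' @export
encode_onehot <- function(bases) {
  chars <- check_alphabet(bases)
  m <- matrix(0L, nrow = length(chars), ncol = 4L,
              dimnames = list(NULL, RNA_BASES))
  idx <- match(chars, RNA_BASES)
  hit <- !is.na(idx)
  m[cbind(which(hit), idx[hit])] <- 1L
  m
}

#' Chemical-property encode an RNA window
#'
#' Three binary properties per nucleotide: ring number (purine A/G = 1,
#' pyrimidine C/U = 0), functional group (amino A/C = 1, keto G/U = 0)
#' and hydrogen-bond strength (weak A/U = 1, strong C/G = 0). So
#' A = (1,1,1), C = (0,1,0), G = (1,0,0), U = (0,0,1); `N` = (0,0,0).
#' The triple uniquely identifies the base.
#'
#' @inheritParams encode_onehot
#' @return An `L x 3` binary matrix with columns `ring`, `amino`, `weak`.
#' @export
encode_chemical <- function(bases) {
  chars <- check_alphabet(bases)
  cbind(
    ring  = as.integer(chars %in% c("A", "G")),
    amino = as.integer(chars %in% c("A", "C")),
    weak  = as.integer(chars %in% c("A", "U"))
  )
}

#' Parse a dot-bracket string into base pairs
#'
#' Stack-based matching. Round parentheses are the usual RNAfold output;
#' square and curly brackets are tolerated as independent families (as
#' emitted by pseudoknot-aware folders), each matched with its own stack.
#'
#' @param db Dot-bracket string over `(`, `)`, `.`, `[`, `]`, `{`, `}`.
#' @return A two-column integer matrix of 0-based pairs `(i, j)` with
#'   `i < j`, ordered by `i`; zero rows if nothing is paired.
#' @examples
#' parse_dotbracket("((...))")
#' @export
parse_dotbracket <- function(db) {
  chars <- strsplit(db, "")[[1]]
  families <- list(c("(", ")"), c("[", "]"), c("{", "}"))
  ok <- chars %in% c(".", unlist(families))
  if (!all(ok)) {
    stop("illegal dot-bracket character '", chars[which(!ok)[1]],
         "' at position ", which(!ok)[1], call. = FALSE)
  }
  pairs <- matrix(integer(0), ncol = 2)
  for (fam in families) {
    stack <- integer(0)
    for (p in seq_along(chars)) {
      if (chars[p] == fam[1]) {
        stack <- c(stack, p)
      } else if (chars[p] == fam[2]) {
        if (length(stack) == 0) {
          stop("unbalanced '", fam[2], "' at position ", p, call. = FALSE)
        }
        pairs <- rbind(pairs, c(stack[length(stack)], p))
        stack <- stack[-length(stack)]
      }
    }
    if (length(stack) > 0) {
      stop("unbalanced '", fam[1], "' at position ", stack[length(stack)],
           call. = FALSE)
    }
  }
  pairs <- pairs - 1L  # 0-based
  pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  colnames(pairs) <- c("i", "j")
  pairs
}

#' Base-pair matrix from a pair list
#'
#' Builds the symmetric binary base-base relationship matrix: entry
#' `(i, j)` and `(j, i)` are 1 exactly when bases i and j are paired.
#'
#' @param pairs Two-column matrix of 0-based pairs (as from
#'   [parse_dotbracket()]).
#' @param L Window length.
#' @return An `L x L` binary symmetric matrix with zero diagonal.
#' @export
pairs_to_matrix <- function(pairs, L) {
  m <- matrix(0L, L, L)
  if (NROW(pairs) > 0) {
    if (any(pairs < 0) || any(pairs >= L)) {
      stop("pair index out of range for L = ", L, call. = FALSE)
    }
    m[cbind(pairs[, 1] + 1L, pairs[, 2] + 1L)] <- 1L
    m[cbind(pairs[, 2] + 1L, pairs[, 1] + 1L)] <- 1L
  }
  m
}

#' Dot-bracket from a structure matrix (inverse of the encoding)
#' @param x_str symmetric binary pair matrix
#' @return dot-bracket string (round brackets only; assumes nested pairs)
#' @keywords internal
matrix_to_dotbracket <- function(x_str) {
  L <- nrow(x_str)
  db <- rep(".", L)
  idx <- which(x_str == 1, arr.ind = TRUE)
  idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
  db[idx[, 1]] <- "("
  db[idx[, 2]] <- ")"
  paste(db, collapse = "")
}

WATSON_CRICK <- list(A = "U", U = c("A", "G"), G = c("C", "U"), C = "G")

can_pair <- function(a, b) b %in% WATSON_CRICK[[a]]

#' Maximum base-pairing fold (Nussinov dynamic program)
#'
#' A deterministic maximum-pairing folder used as the package's built-in
#' structure predictor for synthetic data and as a fallback when no
#' external thermodynamic folder is wired in. Allowed pairs are AU, GC
#' and the GU wobble; hairpin loops must span at least `min_loop`
#' unpaired bases. The traceback is deterministic: position i pairs with
#' the smallest admissible j.
#'
#' Note this maximises the number of pairs, not thermodynamic stability;
#' it is a structural caricature adequate for planting and recovering
#' hairpin signal, not a replacement for an energy-model folder such as
#' RNAfold (see [rnafold_hook()]).
#'
#' @param bases String over `A`/`C`/`G`/`U` (N never pairs).
#' @param min_loop Minimum hairpin loop length (default 3).
#' @return Dot-bracket string of the same length.
#' @examples
#' fold_nussinov("GGGAAACCC")
#' @export
fold_nussinov <- function(bases, min_loop = 3) {
  check_alphabet(bases)
  cpp_nussinov_fold(bases, as.integer(min_loop))
}

#' Encode windows into the three feature views
#'
#' Turns a windows tibble (as produced by [build_windows()] or
#' [simulate_nm()]) into the dense arrays the model consumes: the
#' one-hot view `x_seq` (L x 4 x n), the chemical view `x_chem`
#' (L x 3 x n), and the base-pair view `x_str` (L x L x n). The node
#' feature array `x_node` equals `x_seq`; it is kept separate because it
#' belongs to the structure view (the GAT's node identities), so view
#' ablation can silence the sequence view without blinding the graph.
#'
#' @param windows Tibble with columns `bases`, `dotbracket`, `label`
#'   (and optionally `subtype`). Missing dot-brackets are an error; run
#'   [attach_structures()] first.
#' @return An object of class `nm_encoded`: a list of arrays
#'   `x_seq`, `x_chem`, `x_str`, `x_node`, plus `label` and `subtype`
#'   vectors.
#' @export
encode_windows <- function(windows) {
  stopifnot(is.data.frame(windows), nrow(windows) > 0)
  if (!"dotbracket" %in% names(windows) || anyNA(windows$dotbracket)) {
    stop("all windows need a dotbracket; run attach_structures() first",
         call. = FALSE)
  }
  L <- nchar(windows$bases[1])
  if (any(nchar(windows$bases) != L) || any(nchar(windows$dotbracket) != L)) {
    stop("all windows and dot-brackets must share one length", call. = FALSE)
  }
  n <- nrow(windows)
  x_seq <- array(0, dim = c(L, 4, n))
  x_chem <- array(0, dim = c(L, 3, n))
  x_str <- array(0, dim = c(L, L, n))
  for (s in seq_len(n)) {
    x_seq[, , s] <- encode_onehot(windows$bases[s])
    x_chem[, , s] <- encode_chemical(windows$bases[s])
    x_str[, , s] <- pairs_to_matrix(parse_dotbracket(windows$dotbracket[s]), L)
  }
  structure(
    list(x_seq = x_seq, x_chem = x_chem, x_str = x_str, x_node = x_seq,
         label = as.integer(windows$label),
         subtype = if ("subtype" %in% names(windows)) windows$subtype
                   else rep(NA_character_, n)),
    class = "nm_encoded"
  )
}

#' @export
print.nm_encoded <- function(x, ...) {
  d <- dim(x$x_seq)
  cat("<nm_encoded> ", d[3], " samples, window length ", d[1],
      " (", sum(x$label == 1), " positive / ", sum(x$label == 0),
      " negative)\n", sep = "")
  invisible(x)
}

# index an nm_encoded by sample
subset_encoded <- function(enc, idx) {
  structure(
    list(x_seq = enc$x_seq[, , idx, drop = FALSE],
         x_chem = enc$x_chem[, , idx, drop = FALSE],
         x_str = enc$x_str[, , idx, drop = FALSE],
         x_node = enc$x_node[, , idx, drop = FALSE],
         label = enc$label[idx], subtype = enc$subtype[idx]),
    class = "nm_encoded"
  )
}
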