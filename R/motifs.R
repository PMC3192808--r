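# Polyproline motif detection and linker architecture.
#
# SH3 domains engage proline-rich peptides in two orientations:
#   class I  : [RK]-x-x-P-x-x-P   (basic residue first, N-to-C)
#   class II : P-x-x-P-x-[RK]     (basic residue last)
# Both are scanned as minimal windows (7 and 6 residues respectively);
# overlapping windows of the same class are merged to the leftmost match,
# so the reported spans are deterministic and order-independent.

.MOTIF_PATTERNS <- list(
  I  = list(regex = "^[RK]..P..P", width = 7L),
  II = list(regex = "^P..P.[RK]",  width = 6L)
)

#' Scan a protein sequence for class I/II polyproline motifs
#'
#' Finds all minimal windows matching the class I (`[RK]xxPxxP`) and/or
#' class II (`PxxPx[RK]`) SH3-ligand consensus. Overlapping matches of the
#' same class are merged into the leftmost maximal match, so two motifs of
#' one class never overlap in the output.
#'
#' @param sequence Character scalar; amino-acid sequence using the 20
#'   standard one-letter codes (case-insensitive).
#' @param classes Which motif classes to scan for; subset of `c("I", "II")`.
#' @return A data frame with one row per motif site and columns
#'   `motif_id`, `motif_class`, `start`, `end` (1-based, inclusive) and
#'   `subsequence`, sorted by `start`.
#' @examples
#' scan_motifs("PPPVPPRRR", classes = "II")
#' scan_motifs("TRRHLPSPP", classes = "I")
#' @export
scan_motifs <- function(sequence, classes = c("I", "II")) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence)) {
    stopf("'sequence' must be a single character string")
  }
  classes <- match.arg(classes, c("I", "II"), several.ok = TRUE)
  sequence <- toupper(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% AA_ALPHABET)
  if (length(bad)) {
    stopf("invalid amino-acid character '%s' at position %d",
          chars[bad[1]], bad[1])
  }
  n <- nchar(sequence)

  rows <- list()
  for (cl in classes) {
    pat <- .MOTIF_PATTERNS[[cl]]
    starts <- integer(0)
    if (n >= pat$width) {
      cand <- seq_len(n - pat$width + 1L)
      hit <- vapply(cand, function(s) {
        grepl(pat$regex, substr(sequence, s, s + pat$width - 1L))
      }, logical(1))
      starts <- cand[hit]
    }
    # merge overlapping same-class matches: keep leftmost, drop overlaps
    kept <- integer(0)
    last_end <- 0L
    for (s in starts) {
      if (s > last_end) {
        kept <- c(kept, s)
        last_end <- s + pat$width - 1L
      }
    }
    for (s in kept) {
      e <- s + pat$width - 1L
      rows[[length(rows) + 1L]] <- data.frame(
        motif_class = cl, start = s, end = e,
        subsequence = substr(sequence, s, e),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(motif_class = character(0), start = integer(0),
               end = integer(0), subsequence = character(0),
               stringsAsFactors = FALSE)
  out <- out[order(out$start), , drop = FALSE]
  out <- cbind(motif_id = if (nrow(out)) sprintf("m%02d", seq_len(nrow(out)))
                          else character(0),
               out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Assemble a motif layout with inter-motif linker lengths
#'
#' A layout orders the motif sites along one sequence and records, for each
#' adjacent pair, the number of residues strictly between the two motif
#' spans (the linker length `n` that sets the contour length of the tether).
#'
#' @param sequence_id Identifier for the source sequence.
#' @param sites Data frame of motif sites as returned by [scan_motifs()]
#'   (columns `motif_id`, `motif_class`, `start`, `end` required).
#' @return An object of class `motif_layout`: a list with `sequence_id`,
#'   `sites` (sorted by start) and `linker_lengths` (integer vector of
#'   length `nrow(sites) - 1`).
#' @export
build_layout <- function(sequence_id, sites) {
  req <- c("motif_id", "motif_class", "start", "end")
  if (!is.data.frame(sites) || !all(req %in% names(sites))) {
    stopf("'sites' must be a data frame with columns %s",
          paste(req, collapse = ", "))
  }
  sites <- sites[order(sites$start), , drop = FALSE]
  if (nrow(sites) && any(sites$start > sites$end)) {
    stopf("motif sites must satisfy start <= end")
  }
  if (nrow(sites) > 1L) {
    prev_end <- sites$end[-nrow(sites)]
    next_start <- sites$start[-1L]
    if (any(next_start <= prev_end)) {
      stopf("overlapping motif sites in layout for '%s'", sequence_id)
    }
    linkers <- as.integer(next_start - prev_end - 1L)
  } else {
    linkers <- integer(0)
  }
  rownames(sites) <- NULL
  structure(list(sequence_id = sequence_id, sites = sites,
                 linker_lengths = linkers),
            class = "motif_layout")
}

#' @export
print.motif_layout <- function(x, ...) {
  cat(sprintf("Motif layout for '%s': %d site(s)\n",
              x$sequence_id, nrow(x$sites)))
  print(x$sites)
  if (length(x$linker_lengths)) {
    cat("Linker lengths (aa):", paste(x$linker_lengths, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Per-column identity conservation of a multiple sequence alignment
#'
#' For each alignment column, the fraction of non-gap rows carrying the
#' majority non-gap residue. Gaps (`-`) are excluded from both numerator
#' and denominator; an all-gap column scores 0.
#'
#' @param alignment Character vector of equal-length gapped sequences, or a
#'   `Biostrings::AAStringSet`.
#' @return An object of class `conservation_profile`: a list with
#'   `conservation` (numeric in `[0, 1]`, one per column), `width` and
#'   `n_sequences`.
#' @export
column_conservation <- function(alignment) {
  if (methods::is(alignment, "XStringSet")) {
    alignment <- as.character(alignment)
  }
  if (!is.character(alignment) || length(alignment) < 1L) {
    stopf("'alignment' must be a non-empty character vector")
  }
  widths <- nchar(alignment)
  if (length(unique(widths)) != 1L) {
    stopf("ragged alignment: row lengths %s", paste(unique(widths), collapse = ", "))
  }
  mat <- do.call(rbind, strsplit(toupper(alignment), "", fixed = TRUE))
  cons <- apply(mat, 2L, function(col) {
    col <- col[col != "-"]
    if (!length(col)) return(0)
    max(table(col)) / length(col)
  })
  structure(list(conservation = as.numeric(cons),
                 width = unique(widths),
                 n_sequences = length(alignment)),
            class = "conservation_profile")
}

#' @export
print.conservation_profile <- function(x, ...) {
  cat(sprintf("Conservation profile: %d columns, %d sequences\n",
              x$width, x$n_sequences))
  print(summary(x$conservation))
  invisible(x)
}
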