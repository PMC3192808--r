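# Synthetic-data generators with known ground truth: distance traces that
# emulate MD-derived inter-site distances, motif-bearing disordered
# sequences with prescribed linker lengths, and alignments with a target
# per-column conservation profile.

#' Generate a synthetic inter-site distance trace
#'
#' Emulates a molecular-dynamics measurement of the distance between two
#' bound motif anchor points: frame `k` carries `|mu + eps_k|` with
#' `eps_k` isotropic Gaussian noise of standard deviation `per_axis_sd`
#' per axis, so the distances follow a non-central chi distribution with 3
#' degrees of freedom (scaled by `per_axis_sd`).
#'
#' @param n_frames Number of frames (>= 1).
#' @param mean_offset Mean displacement vector in Angstrom: either a
#'   3-vector or a scalar mean separation (taken along one axis).
#' @param per_axis_sd Per-axis standard deviation in Angstrom (>= 0).
#' @param seed Optional integer seed for reproducibility.
#' @return Data frame with columns `frame` and `distance_A`.
#' @export
gen_distance_trace <- function(n_frames, mean_offset, per_axis_sd,
                               seed = NULL) {
  n_frames <- assert_count(n_frames, "n_frames", min = 1L)
  if (length(mean_offset) == 1L) mean_offset <- c(mean_offset, 0, 0)
  if (length(mean_offset) != 3L || any(!is.finite(mean_offset))) {
    stopf("'mean_offset' must be a finite scalar or 3-vector")
  }
  assert_scalar_number(per_axis_sd, "per_axis_sd", nonneg = TRUE)
  if (!is.null(seed)) set.seed(seed)
  eps <- matrix(stats::rnorm(3L * n_frames, sd = per_axis_sd),
                ncol = 3L)
  disp <- sweep(eps, 2L, mean_offset, "+")
  data.frame(frame = seq_len(n_frames),
             distance_A = sqrt(rowSums(disp^2)))
}

#' Write a distance trace to CSV
#'
#' Counterpart of [read_distance_trace()]; writes the two-column
#' `frame,distance_A` format.
#'
#' @param trace Data frame with columns `frame` and `distance_A`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_trace <- function(trace, path) {
  if (!all(c("frame", "distance_A") %in% names(trace))) {
    stopf("'trace' must have columns 'frame' and 'distance_A'")
  }
  utils::write.csv(trace[, c("frame", "distance_A")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Generate a motif-bearing disordered sequence with known architecture
#'
#' Concatenates motif template peptides separated by background linkers so
#' that the minimal consensus windows inside the templates sit exactly
#' `linker_lengths` residues apart. The background alphabet excludes P, R
#' and K by default, so no unintended class I/II match can arise in the
#' linkers; the realised sequence is re-scanned and the generator fails if
#' the recovered layout differs from the request.
#'
#' @param motifs Character vector of motif template peptides, each
#'   containing exactly one class I or class II consensus window (e.g. the
#'   scaffold peptides `"PPPVPPRRR"` or `"TRRHLPSPP"`).
#' @param linker_lengths Integer vector, one per adjacent template pair:
#'   residues strictly between the two matched consensus windows. Must be
#'   long enough to cover the template residues flanking the windows.
#' @param n_head,n_tail Background residues before the first and after the
#'   last template (default 10 each).
#' @param background Alphabet for linker residues (default: the 20
#'   standard residues minus P, R, K).
#' @param sequence_id Identifier for the generated sequence.
#' @param seed Optional integer seed.
#' @return List with `sequence_id`, `sequence`, `sites` (expected motif
#'   table) and `layout` (the [build_layout()] ground truth).
#' @export
gen_sequence <- function(motifs, linker_lengths = integer(0),
                         n_head = 10L, n_tail = 10L,
                         background = setdiff(AA_ALPHABET, c("P", "R", "K")),
                         sequence_id = "synthetic", seed = NULL) {
  if (!is.character(motifs)) stopf("'motifs' must be a character vector")
  m <- length(motifs)
  if (m >= 1L && length(linker_lengths) != max(m - 1L, 0L)) {
    stopf("'linker_lengths' must have one entry per adjacent motif pair")
  }
  if (length(linker_lengths) && any(linker_lengths < 0)) {
    stopf("linker lengths must be >= 0")
  }
  if (!is.null(seed)) set.seed(seed)
  bg <- function(n) {
    if (n == 0L) "" else
      paste(sample(background, n, replace = TRUE), collapse = "")
  }

  windows <- lapply(motifs, function(tpl) {
    hits <- scan_motifs(tpl)
    if (nrow(hits) != 1L) {
      stopf("motif template '%s' must contain exactly one consensus window (found %d)",
            tpl, nrow(hits))
    }
    hits
  })

  seq_parts <- character(0)
  pos <- 0L
  expected <- list()
  append_part <- function(s) {
    seq_parts <<- c(seq_parts, s)
    pos <<- pos + nchar(s)
  }
  append_part(bg(assert_count(n_head, "n_head", min = 0L)))
  for (k in seq_len(m)) {
    tpl <- motifs[k]
    win <- windows[[k]]
    if (k > 1L) {
      prev_tail <- nchar(motifs[k - 1L]) - windows[[k - 1L]]$end
      this_head <- win$start - 1L
      gap <- linker_lengths[k - 1L] - prev_tail - this_head
      if (gap < 0L) {
        stopf("linker %d (= %d aa) too short for the template flanks (need >= %d)",
              k - 1L, linker_lengths[k - 1L], prev_tail + this_head)
      }
      append_part(bg(gap))
    }
    expected[[k]] <- data.frame(
      motif_class = win$motif_class,
      start = pos + win$start, end = pos + win$end,
      subsequence = win$subsequence, stringsAsFactors = FALSE)
    append_part(tpl)
  }
  append_part(bg(assert_count(n_tail, "n_tail", min = 0L)))
  sequence <- paste(seq_parts, collapse = "")

  found <- scan_motifs(sequence)
  exp_class <- vapply(expected, function(e) e$motif_class, character(1))
  exp_start <- vapply(expected, function(e) e$start, numeric(1))
  exp_end <- vapply(expected, function(e) e$end, numeric(1))
  if (nrow(found) != m ||
      !identical(found$motif_class, exp_class) ||
      !all(found$start == exp_start) || !all(found$end == exp_end)) {
    stopf("generated sequence does not round-trip to the requested layout (spurious or shifted match)")
  }
  list(sequence_id = sequence_id, sequence = sequence, sites = found,
       layout = build_layout(sequence_id, found))
}

#' Generate an alignment with a target conservation profile
#'
#' For each column a consensus residue is drawn and every sequence carries
#' it with the column's target probability, otherwise a uniform draw from
#' the remaining 19 residues; [column_conservation()] on the output
#' recovers the profile up to binomial sampling error.
#'
#' @param profile Numeric vector of per-column target conservation values
#'   in `[1/20, 1]`.
#' @param n_sequences Number of aligned sequences to generate.
#' @param seed Optional integer seed.
#' @return Named character vector of aligned (gap-free) sequences.
#' @export
gen_msa <- function(profile, n_sequences, seed = NULL) {
  if (!is.numeric(profile) || !length(profile) ||
      any(profile < 1 / 20 - 1e-12) || any(profile > 1)) {
    stopf("'profile' values must lie in [1/20, 1]")
  }
  n_sequences <- assert_count(n_sequences, "n_sequences", min = 1L)
  if (!is.null(seed)) set.seed(seed)
  width <- length(profile)
  consensus <- sample(AA_ALPHABET, width, replace = TRUE)
  mat <- matrix("", n_sequences, width)
  for (j in seq_len(width)) {
    take <- stats::runif(n_sequences) < profile[j]
    alt <- sample(setdiff(AA_ALPHABET, consensus[j]),
                  sum(!take), replace = TRUE)
    mat[take, j] <- consensus[j]
    mat[!take, j] <- alt
  }
  out <- apply(mat, 1L, paste, collapse = "")
  names(out) <- sprintf("seq%04d", seq_len(n_sequences))
  out
}
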