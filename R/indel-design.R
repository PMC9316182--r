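#' Globally align two nucleotide sequences
#'
#' Computes a minimal edit script between two sequences under a unit
#' insertion/deletion cost model (Myers shortest-edit-script search, with
#' common prefix/suffix stripping). A mismatched base costs one deletion
#' plus one insertion; adjacent paired deletions/insertions are collapsed
#' to substitution ('S') ops in the returned script. Intended for
#' desk-scale windows (up to ~1 Mb of mostly similar sequence), replacing
#' a whole-genome aligner for InDel screening.
#'
#' @param seq_a,seq_b nucleotide sequences (A/C/G/T/N).
#' @param name_a,name_b sequence names carried into downstream calls.
#' @param max_d abort if the sequences differ by more than this many
#'   insertions+deletions (guards memory on divergent inputs).
#' @return List of class `edit_script`: `ops` (single string over M/S/D/I:
#'   M match, S substitution, D deletion from `seq_a`, I insertion from
#'   `seq_b`), `seq_a`, `seq_b`, `name_a`, `name_b`, `distance`
#'   (insertions + deletions, substitutions counting 2).
#' @export
align_pair <- function(seq_a, seq_b, name_a = "ref", name_b = "alt",
                       max_d = 10000L) {
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  if (nchar(seq_a) == 0L || nchar(seq_b) == 0L)
    stop("both sequences must be non-empty")
  for (s in list(seq_a, seq_b))
    if (grepl("[^ACGTN]", s))
      stop("non-nucleotide characters in input (allowed: A, C, G, T, N)")
  raw <- myers_ops(seq_a, seq_b, as.integer(max_d))
  ops_vec <- strsplit(raw, "")[[1L]]
  # collapse paired del+ins within each maximal gap run into substitutions
  r <- rle(ops_vec %in% c("D", "I"))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  pieces <- character(length(r$lengths))
  for (i in seq_along(r$lengths)) {
    seg <- ops_vec[starts[i]:ends[i]]
    if (!r$values[i]) {
      pieces[i] <- paste(seg, collapse = "")
    } else {
      nd <- sum(seg == "D"); ni <- sum(seg == "I"); k <- min(nd, ni)
      pieces[i] <- paste0(strrep("S", k), strrep("D", nd - k),
                          strrep("I", ni - k))
    }
  }
  ops <- paste(pieces, collapse = "")
  nd <- sum(ops_vec == "D"); ni <- sum(ops_vec == "I")
  out <- list(ops = ops, seq_a = seq_a, seq_b = seq_b,
              name_a = name_a, name_b = name_b, distance = nd + ni)
  class(out) <- "edit_script"
  out
}

#' Apply an edit script to its reference sequence
#'
#' Reconstructs `seq_b` from `seq_a`; used to verify script validity.
#'
#' @param script an `edit_script`.
#' @return The reconstructed alternate sequence.
#' @export
apply_edit_script <- function(script) {
  ops <- strsplit(script$ops, "")[[1L]]
  a <- strsplit(script$seq_a, "")[[1L]]
  b <- strsplit(script$seq_b, "")[[1L]]
  i <- 0L; j <- 0L
  out <- character(length(ops))
  keep <- logical(length(ops))
  for (t in seq_along(ops)) {
    op <- ops[t]
    if (op == "M") { i <- i + 1L; j <- j + 1L; out[t] <- a[i]; keep[t] <- TRUE }
    else if (op == "S") { i <- i + 1L; j <- j + 1L; out[t] <- b[j]; keep[t] <- TRUE }
    else if (op == "D") { i <- i + 1L }
    else if (op == "I") { j <- j + 1L; out[t] <- b[j]; keep[t] <- TRUE }
    else stop("unknown op: ", op)
  }
  if (i != nchar(script$seq_a) || j != nchar(script$seq_b))
    stop("edit script does not span both sequences")
  paste(out[keep], collapse = "")
}

left_align_call <- function(ref, pos, seq) {
  # shift an indel anchored after ref position `pos` left through
  # homopolymer/repeat context; `seq` is the inserted or deleted segment
  len <- nchar(seq)
  while (pos >= 1 && substr(ref, pos, pos) == substr(seq, len, len)) {
    seq <- paste0(substr(ref, pos, pos), substr(seq, 1, len - 1))
    pos <- pos - 1L
  }
  list(pos = pos, seq = seq)
}

#' Extract InDel calls from an edit script
#'
#' A shortest edit script over random sequence can split one biological
#' indel across several gap runs separated by chance matches. Calls are
#' therefore made per variant cluster: the script is segmented at exact
#' match runs of at least `anchor` bp, and each inter-anchor region is
#' re-described by trimming the common prefix and suffix of its reference
#' and alternate substrings. A region whose trimmed remainder is present
#' on one side only becomes a single insertion or deletion; a replacement
#' region yields a co-located deletion and insertion. Calls shorter than
#' `min_len` are discarded. Positions are 1-based and anchor each event at
#' the last reference base preceding it; pure events are left-aligned
#' through repeated sequence context.
#'
#' @param script an `edit_script`.
#' @param min_len minimum event length in bp to report (default 5, the
#'   usual screening threshold for gel-resolvable InDel markers).
#' @param anchor minimum exact-match run (bp) treated as separating two
#'   variant clusters (default 20).
#' @return data.frame with columns `ref_name`, `alt_name`, `ref_pos`,
#'   `length`, `kind` (INSERTION/DELETION), `seq`.
#' @export
call_indels <- function(script, min_len = 5L, anchor = 20L) {
  ops <- strsplit(script$ops, "")[[1L]]
  r <- rle(ops)
  nrun <- length(r$lengths)
  ref_use <- ifelse(r$values %in% c("M", "S", "D"), r$lengths, 0L)
  alt_use <- ifelse(r$values %in% c("M", "S", "I"), r$lengths, 0L)
  ref_end <- cumsum(ref_use); ref_start0 <- ref_end - ref_use  # consumed before
  alt_end <- cumsum(alt_use); alt_start0 <- alt_end - alt_use
  is_anchor <- r$values == "M" & r$lengths >= anchor
  # cluster = maximal stretch of non-anchor runs containing a non-M op
  calls <- list()
  k <- 1L
  while (k <= nrun) {
    if (is_anchor[k]) { k <- k + 1L; next }
    k2 <- k
    while (k2 < nrun && !is_anchor[k2 + 1L]) k2 <- k2 + 1L
    if (any(r$values[k:k2] != "M")) {
      ri0 <- ref_start0[k]; ri1 <- ref_end[k2]
      rj0 <- alt_start0[k]; rj1 <- alt_end[k2]
      ra <- substr(script$seq_a, ri0 + 1L, ri1)
      aa <- substr(script$seq_b, rj0 + 1L, rj1)
      la <- nchar(ra); lb <- nchar(aa)
      p <- 0L
      while (p < min(la, lb) &&
             substr(ra, p + 1L, p + 1L) == substr(aa, p + 1L, p + 1L))
        p <- p + 1L
      s <- 0L
      while (s < min(la, lb) - p &&
             substr(ra, la - s, la - s) == substr(aa, lb - s, lb - s))
        s <- s + 1L
      ra2 <- substr(ra, p + 1L, la - s)
      aa2 <- substr(aa, p + 1L, lb - s)
      if (nchar(ra2) > 0L) {
        d <- list(pos = ri0 + p, seq = ra2)
        if (nchar(aa2) == 0L) d <- left_align_call(script$seq_a, d$pos, d$seq)
        calls[[length(calls) + 1L]] <-
          data.frame(ref_pos = d$pos, length = nchar(ra2), kind = "DELETION",
                     seq = d$seq, stringsAsFactors = FALSE)
      }
      if (nchar(aa2) > 0L) {
        ins <- list(pos = ri0 + p + nchar(ra2), seq = aa2)
        if (nchar(ra2) == 0L)
          ins <- left_align_call(script$seq_a, ins$pos, ins$seq)
        calls[[length(calls) + 1L]] <-
          data.frame(ref_pos = ins$pos, length = nchar(aa2),
                     kind = "INSERTION", seq = ins$seq,
                     stringsAsFactors = FALSE)
      }
    }
    k <- k2 + 1L
  }
  if (length(calls) == 0L) {
    out <- data.frame(ref_name = character(), alt_name = character(),
                      ref_pos = integer(), length = integer(),
                      kind = character(), seq = character(),
                      stringsAsFactors = FALSE)
    return(out)
  }
  out <- do.call(rbind, calls)
  out <- cbind(data.frame(ref_name = script$name_a, alt_name = script$name_b,
                          stringsAsFactors = FALSE), out)
  out <- out[out$length >= min_len, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Prepare InDel marker candidates with flanking sequence
#'
#' Extracts fixed-length flanks around each call from the reference
#' sequence (input for external primer design); calls too close to a
#' sequence end are skipped with a warning. Candidates are named with the
#' chromosome prefix and a sequential ordinal (e.g. `P06gInDel-3`).
#'
#' @param ref_seq the reference sequence the calls are anchored on.
#' @param calls data.frame from [call_indels()].
#' @param flank flank length in bp (default 500).
#' @param chromosome chromosome label used in candidate names (default
#'   "06").
#' @return data.frame with columns `name`, `ref_pos`, `length`, `kind`,
#'   `size_diff_bp`, `left_flank`, `right_flank`.
#' @export
design_candidates <- function(ref_seq, calls, flank = 500L,
                              chromosome = "06") {
  n <- nchar(ref_seq)
  rows <- list()
  for (i in seq_len(nrow(calls))) {
    p <- calls$ref_pos[i]
    ref_span <- if (calls$kind[i] == "DELETION") calls$length[i] else 0L
    left_start <- p - flank + 1L
    right_end <- p + ref_span + flank
    if (left_start < 1L || right_end > n) {
      warning("call at ref position ", p, " is within ", flank,
              " bp of a sequence end; skipped")
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      name = sprintf("P%sgInDel-%d", chromosome, length(rows) + 1L),
      ref_pos = p, length = calls$length[i], kind = calls$kind[i],
      size_diff_bp = calls$length[i],
      left_flank = substr(ref_seq, left_start, p),
      right_flank = substr(ref_seq, p + ref_span + 1L, right_end),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(name = character(), ref_pos = integer(),
                      length = integer(), kind = character(),
                      size_diff_bp = integer(), left_flank = character(),
                      right_flank = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
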