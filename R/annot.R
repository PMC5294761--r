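# Chromatin-state vocabulary. Segmentations use 0-based half-open intervals
# (BED convention); variants are 1-based, so position p lies in [start, end)
# iff start < p <= end.
.state_vocab <- c("TssA", "EnhA", "EnhWk", "Ins", "Tx", "Repr", "TssP",
                  "Quies", "StretchEnh")

.check_segments <- function(segments) {
  segments <- tibble::as_tibble(segments)
  req <- c("chrom", "start", "end", "state", "cell_type")
  miss <- setdiff(req, names(segments))
  if (length(miss))
    stop(sprintf("segment table missing column(s): %s", paste(miss, collapse = ", ")))
  bad <- setdiff(unique(segments$state), .state_vocab)
  if (length(bad))
    stop(sprintf("unknown chromatin state label(s): %s", paste(bad, collapse = ", ")))
  if (any(segments$start >= segments$end)) stop("segments must satisfy start < end")
  segments
}

#' Merge adjacent same-state segments
#'
#' Collapses book-ended or overlapping segments that share (cell type,
#' chromosome, state) into single runs. Segmentation tools emit fragmented
#' runs, so merging must precede any length-based classification; the
#' operation is idempotent.
#'
#' @param segments Tibble with columns `chrom`, `start` (0-based), `end`
#'   (exclusive), `state`, `cell_type`.
#' @return A tibble of merged segments, sorted by (cell_type, chrom, start).
#' @export
merge_segments <- function(segments) {
  segments <- .check_segments(segments)
  if (nrow(segments) == 0) return(segments)
  key <- paste(segments$cell_type, segments$chrom, segments$state, sep = "\r")
  parts <- split(segments, key)
  merged <- lapply(parts, function(p) {
    # 1-based closed ranges; book-ended 0-based intervals become adjacent
    # closed ranges, which reduce() merges by default.
    ir <- IRanges::reduce(IRanges::IRanges(p$start + 1L, p$end))
    tibble::tibble(chrom = p$chrom[1],
                   start = IRanges::start(ir) - 1L,
                   end = IRanges::end(ir),
                   state = p$state[1],
                   cell_type = p$cell_type[1])
  })
  out <- dplyr::bind_rows(merged)
  out[order(out$cell_type, out$chrom, out$start), , drop = FALSE]
}

#' Derive stretch enhancers from a chromatin-state segmentation
#'
#' Stretch enhancers are active-enhancer (`EnhA`) runs strictly longer than
#' 3 kb, a chromatin class enriched for islet regulatory variants. Adjacent
#' `EnhA` records are merged first, so the call is invariant to how the
#' segmentation fragments a run; a run of exactly 3,000 bp is not a stretch
#' enhancer.
#'
#' @param segments Segment tibble as in [merge_segments()].
#' @param min_length Run length in bp that must be exceeded; default 3000.
#' @return Merged `EnhA` segments with `end - start > min_length`, relabeled
#'   `StretchEnh`, keeping their cell type.
#' @export
derive_stretch_enhancers <- function(segments, min_length = 3000) {
  segments <- .check_segments(segments)
  enh <- segments[segments$state == "EnhA", , drop = FALSE]
  if (nrow(enh) == 0) return(enh)
  merged <- merge_segments(enh)
  out <- merged[(merged$end - merged$start) > min_length, , drop = FALSE]
  out$state <- rep("StretchEnh", nrow(out))
  out
}

#' Binary variant-by-annotation matrix from chromatin-state segments
#'
#' One column per (cell type, state) combination present in `states`, named
#' `<cell_type>.<state>`; an entry is 1 iff the variant's 1-based position
#' falls inside a segment of that state in that cell type
#' (`start < pos <= end` against the 0-based half-open segment). Twelve cell
#' types by the three active states EnhA/EnhWk/TssA give the standard 36
#' annotation columns. Optionally, stretch enhancers are derived per cell
#' type and appended as `<cell_type>.StretchEnh` columns (or substituted for
#' the `EnhA` columns with `stretch_mode = "replace"`).
#'
#' @param variants Tibble with `variant_id`, `chrom`, `pos` (1-based).
#' @param segments Segment tibble as in [merge_segments()].
#' @param states Character vector of states to turn into columns.
#' @param stretch Add derived stretch-enhancer columns? Default `FALSE`.
#' @param stretch_mode `"add"` keeps the EnhA columns alongside the stretch
#'   columns; `"replace"` drops them.
#' @return Integer 0/1 matrix, rownames `variant_id`, one column per
#'   annotation; column order is cell type within state, stretch last.
#' @export
build_annotation_matrix <- function(variants, segments,
                                    states = c("EnhA", "EnhWk", "TssA"),
                                    stretch = FALSE,
                                    stretch_mode = c("add", "replace")) {
  stretch_mode <- match.arg(stretch_mode)
  variants <- tibble::as_tibble(variants)
  stopifnot(all(c("variant_id", "chrom", "pos") %in% names(variants)))
  segments <- .check_segments(segments)
  bad <- setdiff(states, .state_vocab)
  if (length(bad))
    stop(sprintf("unknown chromatin state label(s): %s", paste(bad, collapse = ", ")))

  seg_sets <- list(base = segments[segments$state %in% states, , drop = FALSE])
  if (stretch) {
    seg_sets$stretch <- derive_stretch_enhancers(segments)
    if (stretch_mode == "replace")
      seg_sets$base <- seg_sets$base[seg_sets$base$state != "EnhA", , drop = FALSE]
  }
  seg <- dplyr::bind_rows(seg_sets)

  cell_types <- sort(unique(segments$cell_type))
  use_states <- if (stretch && stretch_mode == "replace")
    c(setdiff(states, "EnhA"), "StretchEnh")
  else c(states, if (stretch) "StretchEnh")
  cols <- as.vector(outer(cell_types, use_states, paste, sep = "."))
  mat <- matrix(0L, nrow = nrow(variants), ncol = length(cols),
                dimnames = list(variants$variant_id, cols))

  key <- paste(seg$cell_type, seg$state, sep = ".")
  for (k in unique(key)) {
    if (!k %in% cols) next
    sk <- seg[key == k, , drop = FALSE]
    for (chr in unique(sk$chrom)) {
      vi <- which(variants$chrom == chr)
      if (!length(vi)) next
      sc <- sk[sk$chrom == chr, , drop = FALSE]
      ir <- IRanges::IRanges(sc$start + 1L, sc$end)
      q <- IRanges::IRanges(variants$pos[vi], variants$pos[vi])
      hit <- IRanges::overlapsAny(q, ir)
      mat[vi[hit], k] <- 1L
    }
  }
  mat
}
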