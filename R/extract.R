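#' Extract per-cell mean-intensity traces from an image stack
#'
#' For each positive integer label in the mask, the trace value at frame `t`
#' is the mean of the stack pixels under that label. Label 0 is background
#' and ignored.
#'
#' @param stack A numeric 3-D array `(rows, cols, frames)`.
#' @param mask An integer matrix of the same spatial dimensions; positive
#'   entries are cell labels.
#' @param fs Sampling rate to stamp on the traces (Hz).
#' @return A list of [fluor_trace()] objects, one per label present, named
#'   by label.
#' @export
extract_traces <- function(stack, mask, fs = 5) {
  if (length(dim(stack)) != 3L)
    stop("extract_traces: 'stack' must be a 3-D array (rows, cols, frames)")
  if (!all(dim(stack)[1:2] == dim(mask)))
    stop("extract_traces: stack frames and mask differ in spatial dimensions")
  if (any(mask < 0) || any(mask != round(mask)))
    stop("extract_traces: mask labels must be non-negative integers")
  labs <- sort(unique(as.integer(mask[mask > 0])))
  if (!length(labs)) return(list())

  nt <- dim(stack)[3L]
  flat <- matrix(stack, ncol = nt)    # pixels x frames
  mv <- as.integer(mask)
  fg <- mv > 0L
  sums <- rowsum(flat[fg, , drop = FALSE], group = mv[fg])
  counts <- as.vector(table(mv[fg]))
  means <- sums / counts
  out <- lapply(seq_along(labs), function(i)
    fluor_trace(means[i, ], fs = fs, cell_id = labs[i]))
  names(out) <- labs
  out
}
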