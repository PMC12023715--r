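# GFP-based separation of coculture recordings into tumor (gb) and neuron
# sides: the GFP reference is binarized at its mean intensity and the
# time-lapse is multiplied with the mask and its complement.

#' Binarize a GFP reference image at its mean intensity
#'
#' Pixels strictly greater than the image mean form the tumor-cell mask.
#' A constant image yields an empty mask (with a warning), deterministically.
#'
#' @param gfp numeric matrix (GFP image, same field as the time-lapse).
#' @return A `celltype_mask`: logical `gb_mask` plus `threshold_used`
#'   (the image mean).
#' @export
binarize_gfp <- function(gfp) {
  thr <- mean(gfp)
  mask <- gfp > thr
  if (!any(mask))
    warning("GFP image yields an empty gb mask; unmixing will be degenerate")
  structure(list(gb_mask = mask, threshold_used = thr),
            class = "celltype_mask")
}

#' Split a time-lapse stack into tumor-side and neuron-side stacks
#'
#' Framewise multiplication with the binary mask and its complement:
#' `gb_stack = stack * mask`, `neuron_stack = stack * (1 - mask)`. The two
#' sides reconstruct the input exactly.
#'
#' @param stack a [time_lapse_stack].
#' @param mask a `celltype_mask` from [binarize_gfp()].
#' @return list with elements `gb` and `neuron`, both [time_lapse_stack]s.
#' @export
split_stack <- function(stack, mask) {
  m <- mask$gb_mask
  assert_that(all(dim(m) == dim(stack$data)[1:2]),
              "mask shape does not match the stack")
  tt <- dim(stack$data)[3]
  mul <- array(rep(as.numeric(m), tt), dim = dim(stack$data))
  gb <- stack; gb$data <- stack$data * mul
  neuron <- stack; neuron$data <- stack$data * (1 - mul)
  list(gb = gb, neuron = neuron)
}

#' Classify ROIs as tumor (gb) or neuron by mask overlap
#'
#' An active ROI is labelled `gb` when at least half of its pixels fall in
#' the gb mask, else `neuron` (a 50% tie goes to `gb`). Background ROIs get
#' class `NA`. This per-ROI vote bridges the whole-stack mask separation to
#' per-cell feature tables.
#'
#' @param rois a [roi_set].
#' @param mask a `celltype_mask`.
#' @return data.frame with columns `roi`, `cell_class`, `gb_fraction`.
#' @export
classify_rois <- function(rois, mask) {
  m <- mask$gb_mask
  assert_that(all(dim(m) == rois$shape),
              "mask shape does not match the roi_set")
  h <- nrow(m)
  rows <- lapply(rois$rois, function(r) {
    if (r$kind == "background")
      return(data.frame(roi = r$label, cell_class = NA_character_,
                        gb_fraction = NA_real_, stringsAsFactors = FALSE))
    frac <- mean(m[r$pixels[, 1L] + (r$pixels[, 2L] - 1L) * h])
    data.frame(roi = r$label,
               cell_class = if (frac >= 0.5) "gb" else "neuron",
               gb_fraction = frac, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
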