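#' Labeled tissue image
#'
#' Container for registered binary segmentation masks of one tissue section:
#' extracellular space (ES, from the WGA channel), fibroblasts (vimentin) and
#' myofibroblasts (alpha-SMA). Masks are logical matrices indexed
#' `[row = y, col = x]`; by imaging convention the myocyte long axis runs
#' along x for long-axis sections.
#'
#' @param es_mask,fibroblast_mask,myofibroblast_mask logical matrices of equal
#'   dimension. The fibroblast and myofibroblast masks must be disjoint from
#'   each other and from the ES mask, so that the non-myocyte fraction is the
#'   sum of the three fractions.
#' @param pixel_size_nm pixel edge length in nanometres.
#' @param myocyte_axis `"x-aligned"` for long-axis sections (all four stimulus
#'   edges usable) or `"cross-section"` (transverse conduction only).
#' @param group optional cohort label: `"donor"`, `"IC"` or `"NIC"`.
#' @param provenance free-form origin tag (generator spec or file path).
#'
#' @return An object of class `tissue_image`.
#' @export
tissue_image <- function(es_mask, fibroblast_mask, myofibroblast_mask,
                         pixel_size_nm, myocyte_axis = c("x-aligned", "cross-section"),
                         group = NA_character_, provenance = "in-memory") {
  myocyte_axis <- match.arg(myocyte_axis)
  stopifnot(is.matrix(es_mask), is.matrix(fibroblast_mask), is.matrix(myofibroblast_mask))
  if (!all(dim(es_mask) == dim(fibroblast_mask)) ||
      !all(dim(es_mask) == dim(myofibroblast_mask))) {
    stop("masks must have identical dimensions")
  }
  es <- es_mask != 0
  fb <- fibroblast_mask != 0
  mf <- myofibroblast_mask != 0
  if (any(fb & mf)) stop("fibroblast and myofibroblast masks overlap")
  if (any(es & (fb | mf))) stop("ES mask overlaps fibroblast/myofibroblast masks")
  if (!is.numeric(pixel_size_nm) || pixel_size_nm <= 0) stop("pixel_size_nm must be > 0")
  structure(
    list(
      es = es, fib = fb, myofib = mf,
      pixel_size_nm = as.numeric(pixel_size_nm),
      myocyte_axis = myocyte_axis,
      group = group,
      provenance = provenance
    ),
    class = "tissue_image"
  )
}

#' @export
print.tissue_image <- function(x, ...) {
  d <- dim(x$es)
  um <- d * x$pixel_size_nm / 1000
  cat(sprintf(
    "tissue_image: %d x %d px (%.0f x %.0f um), pixel %.0f nm, axis %s, group %s\n",
    d[1], d[2], um[1], um[2], x$pixel_size_nm, x$myocyte_axis, x$group
  ))
  nm <- mean(x$es | x$fib | x$myofib)
  cat(sprintf("  V_nm (whole image) = %.2f%%\n", 100 * nm))
  invisible(x)
}

#' @export
dim.tissue_image <- function(x) dim(x$es)

#' Write a labeled tissue image to disk
#'
#' Writes the three masks as single-channel 8-bit PNG files
#' (`<prefix>_es.png`, `<prefix>_fib.png`, `<prefix>_myofib.png`) plus a JSON
#' sidecar `<prefix>.json` with pixel size, group and orientation metadata.
#'
#' @param image a [tissue_image()].
#' @param prefix output path prefix (directories must exist).
#' @return Invisibly, the sidecar path.
#' @export
write_tissue_image <- function(image, prefix) {
  stopifnot(inherits(image, "tissue_image"))
  paths <- paste0(prefix, c("_es.png", "_fib.png", "_myofib.png"))
  masks <- list(image$es, image$fib, image$myofib)
  for (i in seq_along(paths)) {
    png::writePNG(matrix(as.numeric(masks[[i]]), nrow = nrow(masks[[i]])), paths[i])
  }
  sidecar <- paste0(prefix, ".json")
  jsonlite::write_json(
    list(
      pixel_size_nm = image$pixel_size_nm,
      myocyte_axis = image$myocyte_axis,
      group = image$group,
      provenance = image$provenance,
      masks = basename(paths)
    ),
    sidecar,
    auto_unbox = TRUE, digits = NA
  )
  invisible(sidecar)
}

#' Read a labeled tissue image written by [write_tissue_image()]
#'
#' @param prefix path prefix used when writing.
#' @return A [tissue_image()].
#' @export
read_tissue_image <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  rd <- function(suffix) {
    m <- png::readPNG(paste0(prefix, suffix))
    if (length(dim(m)) == 3) m <- m[, , 1]
    m > 0.5
  }
  tissue_image(rd("_es.png"), rd("_fib.png"), rd("_myofib.png"),
    pixel_size_nm = meta$pixel_size_nm,
    myocyte_axis = meta$myocyte_axis,
    group = if (is.null(meta$group)) NA_character_ else meta$group,
    provenance = paste0(prefix, ".json")
  )
}
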