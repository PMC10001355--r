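# ISIC-style directory I/O.
#
# Layout: <dir>/images/<id>.png, <dir>/masks/<id>_segmentation.png and
# <dir>/labels.csv with columns image_id, melanoma, seborrheic_keratosis
# (the ISIC-2017 ground-truth dialect: nevus is encoded as both zero).
# Mask PNGs are single-channel 8-bit with {0, 255}.

#' Write a dataset as an ISIC-layout directory
#'
#' @param samples list of `list(image, mask = NULL, label = NULL)`; masks and
#'   labels are written only for the samples that carry them.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_isic_dir <- function(samples, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  has_mask <- any(vapply(samples, function(s) !is.null(s$mask), logical(1)))
  if (has_mask)
    dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (s in samples) {
    id <- s$image$id
    png::writePNG(s$image$pixels, file.path(dir, "images", paste0(id, ".png")))
    if (!is.null(s$mask))
      png::writePNG(matrix(as.numeric(s$mask), nrow(s$mask)),
                    file.path(dir, "masks", paste0(id, "_segmentation.png")))
    if (!is.null(s$label))
      rows[[length(rows) + 1L]] <- data.frame(
        image_id = id,
        melanoma = as.integer(s$label == "melanoma"),
        seborrheic_keratosis = as.integer(s$label == "seborrheic_keratosis"))
  }
  if (length(rows))
    write.csv(do.call(rbind, rows), file.path(dir, "labels.csv"),
              row.names = FALSE)
  invisible(dir)
}

#' Read an ISIC-layout directory
#'
#' @param dir directory produced by [write_isic_dir()] or laid out the same
#'   way (e.g. a prepared ISIC-2017 subset).
#' @return list of `list(image, mask, label)`; `mask`/`label` are `NULL`
#'   when absent.
#' @export
read_isic_dir <- function(dir) {
  img_files <- sort(list.files(file.path(dir, "images"), pattern = "\\.png$"))
  if (!length(img_files)) stop("no images found under ", dir)
  labels <- NULL
  label_file <- file.path(dir, "labels.csv")
  if (file.exists(label_file)) {
    labels <- read.csv(label_file, stringsAsFactors = FALSE)
    rownames(labels) <- labels$image_id
  }
  lapply(img_files, function(f) {
    id <- sub("\\.png$", "", f)
    px <- png::readPNG(file.path(dir, "images", f))
    if (length(dim(px)) == 3L && dim(px)[3] > 3L) px <- px[, , 1:3]
    img <- lesion_image(px, id)
    mask <- NULL
    mf <- file.path(dir, "masks", paste0(id, "_segmentation.png"))
    if (file.exists(mf)) {
      mm <- png::readPNG(mf)
      if (length(dim(mm)) == 3L) mm <- mm[, , 1]
      mask <- as_mask((mm >= 0.5) * 1L)
    }
    label <- NULL
    if (!is.null(labels) && id %in% rownames(labels)) {
      row <- labels[id, ]
      label <- disease_label(
        if (row$melanoma == 1) "melanoma"
        else if (row$seborrheic_keratosis == 1) "seborrheic_keratosis"
        else "nevus")
    }
    list(image = img, mask = mask, label = label)
  })
}
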