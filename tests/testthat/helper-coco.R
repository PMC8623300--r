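# Builders for synthetic COCO-style instance-annotation JSON files.

coco_category_map <- c("flower buds" = "buds",
                       "flowers" = "flowers",
                       "immature fruits" = "immature_fruits",
                       "mature fruits" = "mature_fruits")

# Write a COCO file with the given per-image, per-class instance counts.
# counts: n_images x 4 matrix (buds, flowers, immature, mature).
write_coco_fixture <- function(path, counts, extra_category = NULL) {
  counts <- matrix(counts, ncol = 4)
  n_img <- nrow(counts)
  categories <- data.frame(id = 1:4, name = names(coco_category_map),
                           stringsAsFactors = FALSE)
  if (!is.null(extra_category))
    categories <- rbind(categories,
                        data.frame(id = 5L, name = extra_category))
  ann <- do.call(rbind, lapply(seq_len(n_img), function(i) {
    ks <- rep(1:4, times = counts[i, ])
    if (!length(ks)) return(NULL)
    data.frame(image_id = i, category_id = ks)
  }))
  if (is.null(ann)) ann <- data.frame(image_id = integer(),
                                      category_id = integer())
  ann <- cbind(id = seq_len(nrow(ann)), ann)
  obj <- list(
    images = data.frame(id = seq_len(n_img),
                        file_name = sprintf("sheet%03d.jpg", seq_len(n_img))),
    annotations = ann,
    categories = categories)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, dataframe = "rows")
  path
}

# Deposit-shaped fixture: 21 sheets, class totals 279/349/196/212
# spread deterministically across sheets.
deposit_shaped_counts <- function() {
  totals <- c(279L, 349L, 196L, 212L)
  n_img <- 21L
  sapply(totals, function(tt) {
    base <- tt %/% n_img
    counts <- rep(base, n_img)
    counts[seq_len(tt - base * n_img)] <- base + 1L
    counts
  })
}
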