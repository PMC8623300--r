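# Per-image organ counts from COCO-style instance annotations.

#' Organ counts from a COCO instance-annotation file
#'
#' Reduces a COCO-Annotator-style JSON file (top-level \code{images},
#' \code{annotations}, \code{categories}) to per-image counts of the
#' four organ classes.  Because annotation deposits label categories in
#' free text, a category map translates category names to the canonical
#' classes, e.g. \code{c("flower buds" = "buds", "flowers" = "flowers",
#' "immature fruits" = "immature_fruits", "mature fruits" =
#' "mature_fruits")}.  Images with no annotations get all-zero counts.
#'
#' @param json_path Path to the COCO JSON file.
#' @param category_map Named character vector: names are the category
#'   names in the file, values are canonical classes (see
#'   \code{\link{organ_classes}}).
#' @param strict If \code{TRUE}, a category present in the file but
#'   absent from the map is an error; otherwise its instances are
#'   dropped with a warning.
#' @return data.frame with columns \code{image_id}, \code{buds},
#'   \code{flowers}, \code{immature_fruits}, \code{mature_fruits};
#'   one row per image, in the file's image order.
#' @export
counts_from_coco <- function(json_path, category_map, strict = FALSE) {
  if (!file.exists(json_path))
    stop("COCO file not found: ", json_path, call. = FALSE)
  obj <- tryCatch(jsonlite::fromJSON(json_path, simplifyVector = TRUE),
                  error = function(e)
                    stop("malformed COCO JSON: ", conditionMessage(e),
                         call. = FALSE))
  for (fld in c("images", "annotations", "categories"))
    if (is.null(obj[[fld]]))
      stop("malformed COCO JSON: missing top-level '", fld, "'",
           call. = FALSE)
  bad_class <- setdiff(unname(category_map), .class_names)
  if (length(bad_class))
    stop("category_map targets unknown class(es): ",
         paste(bad_class, collapse = ", "), call. = FALSE)
  cats <- as.data.frame(obj$categories)
  cats$class <- unname(category_map[cats$name])
  unmapped <- cats$name[is.na(cats$class)]
  if (length(unmapped)) {
    msg <- paste("unmapped COCO categor(ies):",
                 paste(unmapped, collapse = ", "))
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  image_ids <- obj$images$id
  out <- data.frame(image_id = image_ids, stringsAsFactors = FALSE)
  for (cl in .class_names) out[[cl]] <- 0L
  ann <- as.data.frame(obj$annotations)
  if (nrow(ann)) {
    ann$class <- cats$class[match(ann$category_id, cats$id)]
    ann <- ann[!is.na(ann$class), , drop = FALSE]
    unknown_img <- setdiff(unique(ann$image_id), image_ids)
    if (length(unknown_img))
      stop("annotation(s) reference unknown image id(s): ",
           paste(unknown_img, collapse = ", "), call. = FALSE)
    if (nrow(ann)) {
      tab <- table(factor(ann$image_id, levels = image_ids),
                   factor(ann$class, levels = .class_names))
      out[.class_names] <- as.data.frame.matrix(tab)
    }
  }
  rownames(out) <- NULL
  out
}
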