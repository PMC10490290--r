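# Annotation formats: Pascal VOC XML <-> normalized YOLO TXT labels.
#
# Convention: VOC pixel corners are 0-based and half-open after conversion,
# i.e. a box (xmin, ymin)-(xmax, ymax) covers pixels [xmin, xmax) x
# [ymin, ymax), so its normalized width is (xmax - xmin) / image_width.

#' Normalized YOLO boxes
#'
#' A `NormBox` table has one row per object: integer `class_id` and reals
#' `cx, cy, w, h` in `[0, 1]` (fractions of the image dims, center/size form).
#'
#' @param class_id integer vector
#' @param cx,cy,w,h normalized center and size
#' @return validated `data.frame` of class `norm_box`
#' @export
norm_box <- function(class_id = integer(0), cx = numeric(0),
                     cy = numeric(0), w = numeric(0), h = numeric(0)) {
  df <- data.frame(class_id = as.integer(class_id), cx = cx, cy = cy,
                   w = w, h = h)
  validate_norm_box(df)
}

validate_norm_box <- function(df) {
  if (nrow(df)) {
    if (any(df$w <= 0) || any(df$h <= 0) || any(df$w > 1) || any(df$h > 1))
      stop("invalid NormBox: w/h must be in (0, 1]")
    if (any(df$cx - df$w / 2 < -1e-9) || any(df$cx + df$w / 2 > 1 + 1e-9) ||
        any(df$cy - df$h / 2 < -1e-9) || any(df$cy + df$h / 2 > 1 + 1e-9))
      stop("invalid NormBox: box extends outside the unit square")
  }
  class(df) <- c("norm_box", "data.frame")
  df
}

#' Read a Pascal VOC XML annotation
#'
#' @param path file path (or an `xml2` document / XML string)
#' @return list with `filename`, `size` (width, height, depth) and `objects`
#'   (data.frame: name, xmin, ymin, xmax, ymax), class `voc_annotation`
#' @export
read_voc_annotation <- function(path) {
  doc <- if (inherits(path, "xml_document")) path else xml2::read_xml(path)
  size_node <- xml2::xml_find_first(doc, ".//size")
  if (inherits(size_node, "xml_missing"))
    stop("VOC parse error: missing <size> in ",
         if (is.character(path)) path else "<document>")
  num <- function(node, what) {
    v <- xml2::xml_find_first(node, what)
    if (inherits(v, "xml_missing"))
      stop("VOC parse error: missing <", what, "> in ",
           if (is.character(path)) path else "<document>")
    as.numeric(xml2::xml_text(v))
  }
  size <- c(width = num(size_node, "width"), height = num(size_node, "height"),
            depth = num(size_node, "depth"))
  objs <- xml2::xml_find_all(doc, ".//object")
  objects <- do.call(rbind, lapply(objs, function(o) {
    bb <- xml2::xml_find_first(o, "bndbox")
    if (inherits(bb, "xml_missing"))
      stop("VOC parse error: object without <bndbox>")
    data.frame(name = xml2::xml_text(xml2::xml_find_first(o, "name")),
               xmin = num(bb, "xmin"), ymin = num(bb, "ymin"),
               xmax = num(bb, "xmax"), ymax = num(bb, "ymax"))
  }))
  if (is.null(objects))
    objects <- data.frame(name = character(0), xmin = numeric(0),
                          ymin = numeric(0), xmax = numeric(0),
                          ymax = numeric(0))
  ann <- list(filename = xml2::xml_text(xml2::xml_find_first(doc, ".//filename")),
              size = size, objects = objects)
  validate_voc(ann)
}

validate_voc <- function(ann) {
  o <- ann$objects
  if (nrow(o)) {
    bad <- o$xmin >= o$xmax | o$ymin >= o$ymax |
           o$xmax > ann$size["width"] | o$ymax > ann$size["height"] |
           o$xmin < 0 | o$ymin < 0
    if (any(bad))
      stop("VOC validation error: box ", which(bad)[1],
           " violates 0 <= xmin < xmax <= width (and same for y)")
  }
  class(ann) <- "voc_annotation"
  ann
}

#' Write a Pascal VOC XML annotation
#' @param ann a `voc_annotation` (see [read_voc_annotation()])
#' @param path output path
#' @export
write_voc_annotation <- function(ann, path) {
  doc <- xml2::xml_new_root("annotation")
  xml2::xml_add_child(doc, "filename", ann$filename %||% "")
  sz <- xml2::xml_add_child(doc, "size")
  xml2::xml_add_child(sz, "width", format(ann$size[["width"]]))
  xml2::xml_add_child(sz, "height", format(ann$size[["height"]]))
  xml2::xml_add_child(sz, "depth", format(ann$size[["depth"]]))
  for (i in seq_len(nrow(ann$objects))) {
    o <- xml2::xml_add_child(doc, "object")
    xml2::xml_add_child(o, "name", ann$objects$name[i])
    bb <- xml2::xml_add_child(o, "bndbox")
    xml2::xml_add_child(bb, "xmin", format(ann$objects$xmin[i]))
    xml2::xml_add_child(bb, "ymin", format(ann$objects$ymin[i]))
    xml2::xml_add_child(bb, "xmax", format(ann$objects$xmax[i]))
    xml2::xml_add_child(bb, "ymax", format(ann$objects$ymax[i]))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Convert VOC pixel boxes to normalized YOLO boxes and back
#'
#' `cx = (xmin + xmax) / 2 / width`, `w = (xmax - xmin) / width` (same for y).
#' @param ann a `voc_annotation`
#' @param class_map named integer vector mapping class names to 0-based ids
#' @return a [norm_box()] table
#' @export
voc_to_yolo <- function(ann, class_map = c(apple = 0L)) {
  o <- ann$objects
  unknown <- setdiff(o$name, names(class_map))
  if (length(unknown))
    stop("unmapped class name(s): ", paste(unknown, collapse = ", "))
  W <- ann$size[["width"]]; H <- ann$size[["height"]]
  norm_box(class_id = unname(class_map[o$name]),
           cx = (o$xmin + o$xmax) / 2 / W, cy = (o$ymin + o$ymax) / 2 / H,
           w = (o$xmax - o$xmin) / W, h = (o$ymax - o$ymin) / H)
}

#' @rdname voc_to_yolo
#' @param boxes a [norm_box()] table
#' @param width,height,depth image size in pixels
#' @param class_names character vector indexed by `class_id + 1`
#' @param filename stored in the annotation
#' @export
yolo_to_voc <- function(boxes, width, height, depth = 3,
                        class_names = "apple", filename = "") {
  o <- data.frame(name = class_names[boxes$class_id + 1L],
                  xmin = round((boxes$cx - boxes$w / 2) * width),
                  ymin = round((boxes$cy - boxes$h / 2) * height),
                  xmax = round((boxes$cx + boxes$w / 2) * width),
                  ymax = round((boxes$cy + boxes$h / 2) * height))
  if (nrow(o)) {
    o$xmax <- pmax(o$xmax, o$xmin + 1); o$ymax <- pmax(o$ymax, o$ymin + 1)
    o$xmin <- pmax(0, pmin(o$xmin, width - 1))
    o$ymin <- pmax(0, pmin(o$ymin, height - 1))
    o$xmax <- pmin(o$xmax, width); o$ymax <- pmin(o$ymax, height)
  }
  validate_voc(list(filename = filename,
                    size = c(width = width, height = height, depth = depth),
                    objects = o))
}

#' Read / write YOLO TXT label files
#'
#' One line per box, `class cx cy w h`, space-separated, 6-decimal fixed
#' format; `read_yolo_txt` is the exact inverse of `write_yolo_txt` (to the
#' 1e-6 quantization of the format).
#' @param boxes a [norm_box()] table
#' @param path file path
#' @export
write_yolo_txt <- function(boxes, path) {
  lines <- sprintf("%d %.6f %.6f %.6f %.6f", boxes$class_id, boxes$cx,
                   boxes$cy, boxes$w, boxes$h)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_yolo_txt
#' @export
read_yolo_txt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(norm_box())
  parsed <- lapply(seq_along(lines), function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    v <- suppressWarnings(as.numeric(f))
    if (length(f) != 5 || anyNA(v))
      stop("malformed YOLO label at ", path, ":", i, ": '", lines[i], "'")
    v
  })
  m <- do.call(rbind, parsed)
  norm_box(class_id = as.integer(m[, 1]), cx = m[, 2], cy = m[, 3],
           w = m[, 4], h = m[, 5])
}
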