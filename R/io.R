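# Readers and writers for the two QuickNII alignment dialects.
#
# JSON dialect: {"name": str, "target": str, "slices": [{"filename", "nr",
#   "width", "height", "anchoring": [ox,oy,oz,ux,uy,uz,vx,vy,vz]}]}.
# XML dialect: <series name="..."><slice filename="..." nr="..." width="..."
#   height="..." anchoring="ox=..&oy=..&..."/></series> with the nine
#   ampersand-joined key=value pairs in fixed order.
#
# The slice "nr" is carried on the anchor as its cutting index so that a
# write/read cycle preserves it; anchors without one are numbered in series
# order on write.

ANCHORING_KEYS <- c("ox", "oy", "oz", "ux", "uy", "uz", "vx", "vy", "vz")

detect_dialect <- function(path, dialect) {
  dialect <- match.arg(dialect, c("auto", "quicknii-json", "quicknii-xml"))
  if (dialect != "auto") return(dialect)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         json = "quicknii-json",
         xml = "quicknii-xml",
         stop("cannot auto-detect dialect from extension '.", ext,
              "'; pass dialect explicitly"))
}

# full-precision decimal text so that write/read round-trips are exact
fmt_num <- function(x) sprintf("%.17g", x)

#' Read a series alignment from a QuickNII file
#'
#' @param path Path to a `.json` or `.xml` alignment file.
#' @param dialect `"auto"` (by extension), `"quicknii-json"` or
#'   `"quicknii-xml"`.
#' @return A [series_alignment()].
#' @export
read_series <- function(path, dialect = "auto") {
  dialect <- detect_dialect(path, dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "quicknii-json") read_series_json(path) else read_series_xml(path)
}

#' Write a series alignment to a QuickNII file
#'
#' @param series A [series_alignment()].
#' @param path Output path.
#' @param dialect See [read_series()].
#' @param meta Optional named list recorded under a `"meta"` key (JSON
#'   dialect only); ignored by readers.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path, dialect = "auto", meta = NULL) {
  stopifnot(inherits(series, "series_alignment"))
  dialect <- detect_dialect(path, dialect)
  if (dialect == "quicknii-json") {
    write_series_json(series, path, meta)
  } else {
    write_series_xml(series, path)
  }
  invisible(path)
}

slice_nr <- function(anchor, fallback) {
  if (is.na(anchor$cutting_index)) fallback else anchor$cutting_index
}

read_series_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$slices)) stop("JSON alignment file has no 'slices' array: ", path)
  sections <- lapply(seq_along(doc$slices), function(k) {
    sl <- doc$slices[[k]]
    fn <- if (is.null(sl$filename)) sprintf("<slice %d>", k) else sl$filename
    for (field in c("filename", "width", "height", "anchoring")) {
      if (is.null(sl[[field]])) {
        stop(sprintf("slice %s: missing '%s'", fn, field))
      }
    }
    anch <- suppressWarnings(as.numeric(unlist(sl$anchoring)))
    if (length(anch) != 9 || any(is.na(anch))) {
      stop(sprintf("slice %s: anchoring must be 9 numeric components", fn))
    }
    nr <- if (is.null(sl$nr)) NA_integer_ else as.integer(sl$nr)
    section_anchor(filename = sl$filename,
                   o = anch[1:3], u = anch[4:6], v = anch[7:9],
                   width = sl$width, height = sl$height, cutting_index = nr)
  })
  series_alignment(name = if (is.null(doc$name)) "series" else doc$name,
                   sections = sections,
                   target = if (is.null(doc$target)) "ABA_Mouse_CCFv3_2017_25um" else doc$target)
}

write_series_json <- function(series, path, meta = NULL) {
  slices <- lapply(seq_along(series$sections), function(k) {
    a <- series$sections[[k]]
    list(filename = a$filename,
         nr = slice_nr(a, k),
         width = a$width,
         height = a$height,
         anchoring = I(unname(anchor_components(a))))
  })
  doc <- list(name = series$name, target = series$target, slices = slices)
  if (!is.null(meta)) doc$meta <- meta
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17))
}

read_series_xml <- function(path) {
  doc <- xml2::read_xml(path)
  if (xml2::xml_name(doc) != "series") stop("root element must be <series>: ", path)
  nodes <- xml2::xml_find_all(doc, "./slice")
  sections <- lapply(seq_along(nodes), function(k) {
    nd <- nodes[[k]]
    fn <- xml2::xml_attr(nd, "filename")
    if (is.na(fn)) stop(sprintf("slice %d: missing 'filename' attribute", k))
    for (at in c("width", "height", "anchoring")) {
      if (is.na(xml2::xml_attr(nd, at))) {
        stop(sprintf("slice %s: missing '%s' attribute", fn, at))
      }
    }
    anch <- parse_anchoring_string(xml2::xml_attr(nd, "anchoring"), fn)
    nr <- xml2::xml_attr(nd, "nr")
    nr <- if (is.na(nr)) NA_integer_ else as.integer(nr)
    section_anchor(filename = fn,
                   o = anch[1:3], u = anch[4:6], v = anch[7:9],
                   width = as.integer(xml2::xml_attr(nd, "width")),
                   height = as.integer(xml2::xml_attr(nd, "height")),
                   cutting_index = nr)
  })
  nm <- xml2::xml_attr(doc, "name")
  tg <- xml2::xml_attr(doc, "target")
  series_alignment(name = if (is.na(nm)) "series" else nm,
                   sections = sections,
                   target = if (is.na(tg)) "ABA_Mouse_CCFv3_2017_25um" else tg)
}

parse_anchoring_string <- function(s, filename) {
  parts <- strsplit(s, "&", fixed = TRUE)[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- vapply(kv, function(p) if (length(p) == 2) p[2] else NA_character_,
                 character(1))
  missing <- setdiff(ANCHORING_KEYS, keys)
  if (length(missing) > 0) {
    stop(sprintf("slice %s: anchoring string missing '%s'",
                 filename, paste(missing, collapse = "', '")))
  }
  out <- suppressWarnings(as.numeric(vals[match(ANCHORING_KEYS, keys)]))
  if (any(is.na(out))) {
    bad <- ANCHORING_KEYS[is.na(out)]
    stop(sprintf("slice %s: non-numeric anchoring component '%s'",
                 filename, paste(bad, collapse = "', '")))
  }
  out
}

write_series_xml <- function(series, path) {
  doc <- xml2::xml_new_root("series", name = series$name, target = series$target)
  for (k in seq_along(series$sections)) {
    a <- series$sections[[k]]
    comp <- anchor_components(a)
    anch <- paste(ANCHORING_KEYS, fmt_num(unname(comp)), sep = "=", collapse = "&")
    xml2::xml_add_child(doc, "slice",
                        filename = a$filename,
                        nr = as.character(slice_nr(a, k)),
                        width = as.character(a$width),
                        height = as.character(a$height),
                        anchoring = anch)
  }
  xml2::write_xml(doc, path)
}
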