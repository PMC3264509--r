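# JSON scene format — the package's native serialisation of a drawing
# (format_version 1). Field names mirror the model types: atoms carry id,
# element, position {x, y}, charge, mass_number, atomic_number_display,
# color [r, g, b], opacity and an optional shell {radii, gradient}.

SCENE_FORMAT_VERSION <- 1L

#' Write a drawing to the JSON scene format
#'
#' @param d a `chem_drawing`.
#' @param path optional file path; when `NULL` the JSON text is returned.
#' @return the JSON string (invisibly when written to `path`).
#' @export
write_scene <- function(d, path = NULL) {
  validate_drawing(d)
  a <- d$atoms
  atoms <- lapply(seq_len(nrow(a)), function(i) {
    rec <- list(id = a$id[i], element = a$element[i],
                position = list(x = a$x[i], y = a$y[i]),
                charge = a$charge[i],
                color = c(a$red[i], a$green[i], a$blue[i]),
                opacity = a$opacity[i])
    if (!is.na(a$mass_number[i])) rec$mass_number <- a$mass_number[i]
    if (!is.na(a$atomic_number_display[i])) rec$atomic_number_display <- a$atomic_number_display[i]
    sh <- d$shells[[as.character(a$id[i])]]
    if (!is.null(sh)) rec$shell <- list(radii = sh$radii, gradient = list(sh$inner, sh$outer))
    rec
  })
  b <- d$bonds
  bonds <- lapply(seq_len(nrow(b)), function(i) {
    list(a1 = b$a1[i], a2 = b$a2[i], kind = b$kind[i],
         color = c(b$red[i], b$green[i], b$blue[i]), opacity = b$opacity[i])
  })
  annotations <- lapply(d$annotations, function(an) {
    rec <- list(shape = an$shape)
    if (!is.null(an$outline)) rec$outline <- unname(apply(an$outline, 1, as.list))
    if (!is.null(an$gradient)) rec$gradient <- an$gradient
    if (!is.null(an$label)) rec$label <- an$label
    rec
  })
  obj <- list(format_version = SCENE_FORMAT_VERSION, atoms = atoms, bonds = bonds,
              annotations = annotations)
  if (!is.null(d$background)) {
    obj$background <- list(image_path = d$background$image_path,
                           brightness = d$background$brightness)
  }
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(as.character(txt)))
  }
  as.character(txt)
}

#' Read a drawing from the JSON scene format
#'
#' @param x a file path or a JSON string.
#' @return a `chem_drawing`.
#' @export
read_scene <- function(x) {
  txt <- if (length(x) == 1L && !grepl("[{\n]", x) && file.exists(x)) {
    paste(readLines(x, warn = FALSE), collapse = "\n")
  } else paste(x, collapse = "\n")
  obj <- tryCatch(jsonlite::fromJSON(txt, simplifyVector = FALSE),
                  error = function(e) cm_abort("chemmorph_format_error",
                                               paste("invalid scene JSON:", conditionMessage(e))))
  if (is.null(obj$format_version) || obj$format_version != SCENE_FORMAT_VERSION) {
    cm_abort("chemmorph_format_error", "missing or unsupported scene format_version")
  }
  atoms <- lapply(obj$atoms, function(rec) {
    atom(id = rec$id, element = rec$element,
         x = rec$position$x, y = rec$position$y,
         charge = if (is.null(rec$charge)) 0L else rec$charge,
         mass_number = rec$mass_number,
         atomic_number_display = rec$atomic_number_display,
         color = if (is.null(rec$color)) c(0L, 0L, 0L) else unlist(rec$color),
         opacity = if (is.null(rec$opacity)) 1 else rec$opacity,
         shell = if (is.null(rec$shell)) NULL else
           shell_style(unlist(rec$shell$radii),
                       unlist(rec$shell$gradient[[1]]),
                       unlist(rec$shell$gradient[[2]])))
  })
  bonds <- lapply(obj$bonds, function(rec) {
    bond(rec$a1, rec$a2, kind = if (is.null(rec$kind)) "single" else rec$kind,
         color = if (is.null(rec$color)) c(0L, 0L, 0L) else unlist(rec$color),
         opacity = if (is.null(rec$opacity)) 1 else rec$opacity)
  })
  annotations <- lapply(obj$annotations, function(rec) {
    outline <- if (is.null(rec$outline)) NULL else
      do.call(rbind, lapply(rec$outline, function(p) c(p[[1]], p[[2]])))
    gradient <- if (is.null(rec$gradient)) NULL else
      list(unlist(rec$gradient[[1]]), unlist(rec$gradient[[2]]))
    annotation(rec$shape, outline = outline, gradient = gradient, label = rec$label)
  })
  background <- if (is.null(obj$background)) NULL else
    background_spec(obj$background$image_path,
                    if (is.null(obj$background$brightness)) 1 else obj$background$brightness)
  drawing(atoms = atoms, bonds = bonds, annotations = annotations, background = background)
}
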