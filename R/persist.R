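#' Save and load a fitted model as plain text
#'
#' Models persist to a documented key-value text format: a header with the
#' fitting configuration (`n_max`, `window`, aggregation, smoothing, class
#' list and per-class counts), the calibration support points, and one line
#' per descriptor with its `Ni` and per-class `Nik` counts.  The training
#' FoT table is not persisted, so leave-one-out operations are unavailable
#' on a loaded model; prediction and extraction are unaffected.
#'
#' @param model A fitted [cner()] model.
#' @param path Output file path.
#' @export
write_cner_model <- function(model, path) {
  stopifnot(inherits(model, "cner_model"))
  hdr <- c("#bayescner-model v1",
           paste0("n_max\t", model$n_max),
           paste0("window\t", model$window),
           paste0("aggregate\t", model$aggregate),
           paste0("alpha\t", format(model$alpha, digits = 17)),
           paste0("N\t", model$N),
           paste0("classes\t", paste(names(model$Nk), collapse = ",")),
           paste0("Nk\t", paste(model$Nk, collapse = ",")))
  cal <- model$calibration
  if (!is.null(cal)) {
    fmt <- function(v) paste(format(v, digits = 17), collapse = ",")
    hdr <- c(hdr,
             paste0("calib_method\t", cal$method),
             paste0("calib_bins\t", cal$bins),
             paste0("calib_pc_x\t", fmt(cal$pc$x)),
             paste0("calib_pc_y\t", fmt(cal$pc$y)),
             paste0("calib_pc_w\t", fmt(cal$pc$w)),
             paste0("calib_pnc_x\t", fmt(cal$pnc$x)),
             paste0("calib_pnc_y\t", fmt(cal$pnc$y)),
             paste0("calib_pnc_w\t", fmt(cal$pnc$w)))
    if (!is.null(cal$pc$coef)) {
      hdr <- c(hdr, paste0("calib_pc_coef\t", fmt(cal$pc$coef)),
               paste0("calib_pnc_coef\t", fmt(cal$pnc$coef)))
    }
  }
  grams <- paste(model$levels, model$Ni,
                 apply(model$Nik, 1L, paste, collapse = ","), sep = "\t")
  .write_utf8_lines(c(hdr, "#grams", grams), path)
  invisible(path)
}

#' @rdname write_cner_model
#' @return `read_cner_model()`: a `"cner_model"` object without training
#'   FoTs.
#' @export
read_cner_model <- function(path) {
  lines <- .read_utf8_lines(path)
  if (!identical(lines[1L], "#bayescner-model v1")) {
    stop("not a bayescner model file: ", path)
  }
  split_at <- match("#grams", lines)
  if (is.na(split_at)) stop("corrupt model file: missing #grams section")
  kv <- strsplit(lines[2:(split_at - 1L)], "\t", fixed = TRUE)
  h <- stats::setNames(vapply(kv, `[`, character(1), 2L),
                       vapply(kv, `[`, character(1), 1L))
  num <- function(key) as.numeric(strsplit(h[[key]], ",", fixed = TRUE)[[1]])
  classes <- strsplit(h[["classes"]], ",", fixed = TRUE)[[1]]

  gl <- strsplit(lines[(split_at + 1L):length(lines)], "\t", fixed = TRUE)
  gl <- gl[lengths(gl) == 3L]
  levels <- vapply(gl, `[`, character(1), 1L)
  Ni <- as.integer(vapply(gl, `[`, character(1), 2L))
  Nik <- t(vapply(gl, function(f) {
    as.integer(strsplit(f[3L], ",", fixed = TRUE)[[1]])
  }, integer(length(classes))))
  colnames(Nik) <- classes

  cal <- NULL
  if ("calib_method" %in% names(h)) {
    cal <- structure(list(
      method = h[["calib_method"]],
      bins = as.integer(h[["calib_bins"]]),
      degree = NA_integer_,
      pc = list(x = num("calib_pc_x"), y = num("calib_pc_y"),
                w = num("calib_pc_w"),
                coef = if ("calib_pc_coef" %in% names(h))
                  num("calib_pc_coef") else NULL),
      pnc = list(x = num("calib_pnc_x"), y = num("calib_pnc_y"),
                 w = num("calib_pnc_w"),
                 coef = if ("calib_pnc_coef" %in% names(h))
                   num("calib_pnc_coef") else NULL)
    ), class = "cner_calibration")
  }
  structure(list(levels = levels, Ni = Ni, Nik = Nik,
                 N = as.integer(h[["N"]]),
                 Nk = stats::setNames(as.numeric(num("Nk")), classes),
                 n_max = as.integer(h[["n_max"]]),
                 window = as.integer(h[["window"]]),
                 aggregate = h[["aggregate"]],
                 alpha = as.numeric(h[["alpha"]]),
                 fots = NULL, long = NULL, calibration = cal),
            class = "cner_model")
}
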