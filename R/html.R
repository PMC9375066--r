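#' Render per-character predictions as coloured HTML
#'
#' Wraps every character of `text` in a colour interpolated between three
#' anchor colours: light green (`#90EE90`) for `Pc = 1, Pnc = 0`, light red
#' (`#F08080`) for `Pnc = 1, Pc = 0`, and blue (`#0000FF`) when both are
#' close to zero.  Intermediate values are mixed barycentrically with
#' weights `(Pc, Pnc, 1 - max(Pc, Pnc))`.  Runs of equal colour share one
#' `<span>`; the text content of the output (after entity unescaping)
#' equals the input exactly.
#'
#' @param text Document text (single string).
#' @param pc,pnc Numeric vectors in `[0, 1]`, one value per character of
#'   `text`.
#' @param standalone Wrap the markup in a minimal HTML document (default
#'   TRUE).
#' @return A single character string of HTML.
#' @export
render_colored_html <- function(text, pc, pnc, standalone = TRUE) {
  n <- nchar(text)
  if (length(pc) != n || length(pnc) != n) {
    stop("need one (pc, pnc) pair per character: text has ", n,
         " characters, got ", length(pc), "/", length(pnc), " values")
  }
  stopifnot(all(pc >= 0 & pc <= 1), all(pnc >= 0 & pnc <= 1))
  if (n == 0L) {
    body <- ""
  } else {
    cols <- .mix_colors(pc, pnc)
    chars <- substring(text, 1:n, 1:n)
    run <- cumsum(c(TRUE, cols[-1L] != cols[-n]))
    body <- paste(vapply(split(seq_len(n), run), function(i) {
      paste0("<span style=\"color:", cols[i[1L]], "\">",
             .html_escape(paste(chars[i], collapse = "")), "</span>")
    }, character(1)), collapse = "")
  }
  if (!standalone) return(body)
  paste0("<!DOCTYPE html>\n<html><head><meta charset=\"utf-8\"/>",
         "<title>CNER colouring</title></head>\n",
         "<body><pre style=\"white-space:pre-wrap\">", body,
         "</pre></body></html>\n")
}

# barycentric mix of the three anchors over weights (pc, pnc, 1 - max)
.mix_colors <- function(pc, pnc) {
  anchors <- grDevices::col2rgb(c("#90EE90", "#F08080", "#0000FF"))
  wb <- 1 - pmax(pc, pnc)
  w <- rbind(pc, pnc, wb)
  tot <- colSums(w)
  tot[tot == 0] <- 1
  mixed <- anchors %*% w / rep(tot, each = 3L)
  grDevices::rgb(t(round(mixed)), maxColorValue = 255)
}

.html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Colour a document by per-character model predictions
#'
#' Scores every character of a text with [predict_position()] (characters
#' outside any token get the enclosing-token scores of none and are
#' rendered with `pc = pnc = 0`) and renders the result with
#' [render_colored_html()].
#'
#' @param model A fitted, calibrated [cner()] model.
#' @param text Plain text to colour.
#' @inheritParams render_colored_html
#' @return HTML string.
#' @export
colorize_text <- function(model, text, standalone = TRUE) {
  n <- nchar(text)
  pc <- numeric(n)
  pnc <- numeric(n)
  tok <- wp_tokenize(text)
  for (i in seq_len(nrow(tok))) {
    for (j in seq_len(tok$end[i] - tok$start[i])) {
      p <- predict_position(model, tok$surface[i], j - 1L)
      pc[tok$start[i] + j] <- p[["pc"]]
      pnc[tok$start[i] + j] <- p[["pnc"]]
    }
  }
  render_colored_html(text, pc, pnc, standalone = standalone)
}
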