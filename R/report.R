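# Text and JSON rendering of test results. Both formats are produced from the
# same plain report list so a JSON round trip re-renders to identical text.

fmt3 <- function(x) ifelse(is.na(x), "NA", sprintf("%.3f", round(x, 3)))

#' Convert a test result to a plain report list
#'
#' Strips a [bf_test()] result down to plain vectors, matrices and tables
#' (full precision, no S3 internals). This list is what [bf_report()]
#' serialises to JSON and what the text renderer consumes, so results can be
#' stored, reloaded and re-rendered without loss.
#'
#' @param x a `"bf_test"` object.
#' @return A named list.
#' @export
as_report_list <- function(x) {
  stopifnot(inherits(x, "bf_test"))
  out <- list(type = x$type,
              labels = x$hypotheses$label,
              hypotheses = x$hypotheses$text,
              prior_prob = unname(x$prior_prob),
              mcrep = x$mcrep,
              seed = if (is.null(x$seed)) NA_integer_ else as.integer(x$seed),
              complement_added = x$complement_added)
  if (x$type == "confirmatory") {
    out$b_u <- unname(x$b_u)
    out$post_prob <- unname(x$post_prob)
    out$bf_matrix <- unname(as.matrix(x$BF_matrix))
    out$computation <- unname(as.matrix(x$BF_computation))
    out$computation_cols <- colnames(x$BF_computation)
    if (!is.null(x$BFu_CI)) {
      out$intervals <- unname(as.matrix(x$BFu_CI))
      out$interval_cols <- colnames(x$BFu_CI)
    }
  } else {
    out$coef_names <- rownames(x$post_prob)
    out$post_prob <- unname(x$post_prob)
    out$bf_matrix <- lapply(x$BF_matrix, unname)
  }
  out
}

render_matrix <- function(M, rnames, cnames, indent = "") {
  M <- matrix(fmt3(M), nrow = length(rnames))
  wide <- pmax(nchar(cnames), apply(nchar(M), 2, max))
  pad <- function(v, w) mapply(function(s, width) formatC(s, width = width),
                               v, w, USE.NAMES = FALSE)
  rw <- max(nchar(rnames))
  head <- paste0(indent, strrep(" ", rw), "  ",
                 paste(pad(cnames, wide), collapse = "  "))
  body <- vapply(seq_along(rnames), function(i)
    paste0(indent, formatC(rnames[i], width = rw, flag = "-"), "  ",
           paste(pad(M[i, ], wide), collapse = "  ")),
    character(1))
  c(head, body)
}

render_report_text <- function(r) {
  lines <- c("Hypotheses:", "")
  lines <- c(lines, paste0("  ", r$labels, ": \"", r$hypotheses, "\""), "")
  if (identical(r$type, "confirmatory")) {
    lines <- c(lines, "Posterior probability of each hypothesis (rounded):", "",
               paste0("  ", r$labels, ": ", fmt3(r$post_prob)), "")
  } else {
    lines <- c(lines,
               "Posterior probabilities for each variable (rounded),",
               "assuming equal prior probabilities:", "")
    lines <- c(lines, render_matrix(r$post_prob, r$coef_names,
                                    r$hypotheses, "  "), "")
  }
  lines
}

render_supplement_text <- function(r) {
  lines <- character()
  if (identical(r$type, "confirmatory")) {
    lines <- c(lines, "BF_matrix:",
               render_matrix(r$bf_matrix, r$labels, r$labels, "  "), "")
    lines <- c(lines, "BF_computation:",
               render_matrix(r$computation, r$labels, r$computation_cols,
                             "  "),
               "  Cells with \"NA\" indicate that a column is \"Not Available\"",
               "  to that hypothesis.", "")
    if (!is.null(r$intervals)) {
      lines <- c(lines, "BFu_CI (90% credibility interval of the numerical",
                 "Bayes factor estimate; printed only when Monte Carlo was used):",
                 render_matrix(r$intervals, r$labels, r$interval_cols, "  "),
                 "")
    }
  } else {
    for (j in seq_along(r$coef_names)) {
      lines <- c(lines, paste0("BF_matrix for ", r$coef_names[j], ":"),
                 render_matrix(r$bf_matrix[[j]], r$labels, r$labels, "  "), "")
    }
  }
  lines
}

#' Render a test result as text or JSON
#'
#' `format = "text"` reproduces the printed blocks (hypothesis list, rounded
#' posterior probabilities, pairwise Bayes factor matrix, the fit/complexity
#' computation table with `NA` for inapplicable cells, and the credibility
#' interval block only when Monte Carlo was used). `format = "json"` emits the
#' same content at full precision; reloading the JSON and re-rendering yields
#' byte-identical text.
#'
#' @param x a `"bf_test"` object.
#' @param format `"text"` or `"json"`.
#' @return A single string.
#' @export
bf_report <- function(x, format = c("text", "json")) {
  format <- match.arg(format)
  r <- as_report_list(x)
  if (format == "json")
    return(as.character(jsonlite::toJSON(r, digits = NA, auto_unbox = TRUE,
                                         na = "null")))
  paste(c(render_report_text(r), render_supplement_text(r)), collapse = "\n")
}

#' Re-render a JSON report as text
#'
#' Reloads the JSON produced by `bf_report(x, "json")` and renders the same
#' text report; the output is identical to `bf_report(x, "text")`.
#'
#' @param json a JSON string.
#' @return A single string.
#' @export
bf_report_from_json <- function(json) {
  r <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  if (identical(r$type, "confirmatory")) {
    r$bf_matrix <- as.matrix(r$bf_matrix)
    r$computation <- as.matrix(r$computation)
    if (!is.null(r$intervals)) r$intervals <- as.matrix(r$intervals)
  } else {
    r$post_prob <- as.matrix(r$post_prob)
    r$bf_matrix <- lapply(r$bf_matrix, as.matrix)
  }
  paste(c(render_report_text(r), render_supplement_text(r)), collapse = "\n")
}

#' @describeIn bf_test Print the hypothesis list and rounded posterior
#'   probabilities (the paper-style primary output block).
#' @export
print.bf_test <- function(x, ...) {
  cat(paste(render_report_text(as_report_list(x)), collapse = "\n"), "\n")
  invisible(x)
}

#' Summarise a constrained-hypothesis Bayes factor test
#'
#' Prints the primary output plus the supplementary blocks: the pairwise
#' Bayes factor matrix, the fit/complexity computation table (`c(E)`,
#' `c(I|E)`, `c`, `f(E)`, `f(I|E)`, `f`, `B(t,u)`, `PP(t)`), and the 90%
#' credibility intervals of the numerical Bayes factor estimates whenever
#' Monte Carlo was involved.
#'
#' @param object a `"bf_test"` object.
#' @param ... unused.
#' @return `object`, invisibly.
#' @export
summary.bf_test <- function(object, ...) {
  cat(bf_report(object, "text"), "\n")
  invisible(object)
}
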