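# Hypothesis constraint mini-language.
#
# Grammar (whitespace ignored):
#   spec       := hypothesis (";" hypothesis)*
#   hypothesis := chain ("&" chain)*
#   chain      := term (cmp term)+          cmp in {"<", ">", "="}
#   term       := group | atom
#   group      := "(" name ("," name)* ")"
#   atom       := name ["-" name] | ["-"] number
#
# Each ADJACENT comparison contributes rows in difference form: "a > b" becomes
# (e_a - e_b)' beta > const(b) - const(a); "<" is mirrored to ">"; "=" gives an
# equality row. A group expands to one row per member against the adjacent
# term. Chains bind only adjacent pairs, so "b1 = b2 = b3 > 0" yields equality
# rows b1-b2=0 and b2-b3=0 plus the single inequality b3>0.

TOK_PATTERNS <- c(name = "^[A-Za-z.][A-Za-z0-9._]*",
                  num  = "^([0-9]+\\.?[0-9]*|\\.[0-9]+)",
                  sym  = "^[(),<>=&;-]")

tokenize_hyp <- function(txt) {
  # the intercept's column name contains parentheses; shield it from the lexer
  txt <- gsub("(Intercept)", ".Intercept.", txt, fixed = TRUE)
  txt <- gsub("[[:space:]]+", "", txt)
  toks <- list(); i <- 1L
  while (nchar(txt) > 0L) {
    hit <- FALSE
    for (type in names(TOK_PATTERNS)) {
      m <- regmatches(txt, regexpr(TOK_PATTERNS[[type]], txt))
      if (length(m) == 1L) {
        val <- m
        if (type == "name" && val == ".Intercept.") val <- "(Intercept)"
        toks[[i]] <- list(type = if (type == "sym") val else type, value = val)
        txt <- substr(txt, nchar(m) + 1L, nchar(txt))
        i <- i + 1L; hit <- TRUE
        break
      }
    }
    if (!hit) stop("cannot tokenize hypothesis near: '", txt, "'")
  }
  toks
}

# An atom is a linear form w'beta + const with w having at most two +/-1 entries.
parse_term <- function(toks, pos, coef_names) {
  k <- length(coef_names)
  atom_name <- function(nm) {
    if (!nm %in% coef_names)
      stop("unknown coefficient '", nm, "'; valid names: ",
           paste(coef_names, collapse = ", "))
    w <- numeric(k); w[match(nm, coef_names)] <- 1
    list(w = w, const = 0)
  }
  tk <- function(p) if (p <= length(toks)) toks[[p]] else list(type = "<end>", value = "")
  t0 <- tk(pos)
  if (t0$type == "(") {
    atoms <- list(); p <- pos + 1L
    repeat {
      nmtok <- tk(p)
      if (nmtok$type != "name") stop("malformed group: expected a coefficient name")
      atoms[[length(atoms) + 1L]] <- atom_name(nmtok$value)
      p <- p + 1L
      sep <- tk(p)
      if (sep$type == ",") { p <- p + 1L; next }
      if (sep$type == ")") { p <- p + 1L; break }
      stop("malformed group: expected ',' or ')'")
    }
    return(list(atoms = atoms, pos = p))
  }
  if (t0$type == "-") {
    numtok <- tk(pos + 1L)
    if (numtok$type != "num") stop("expected a number after unary '-'")
    return(list(atoms = list(list(w = numeric(k), const = -as.numeric(numtok$value))),
                pos = pos + 2L))
  }
  if (t0$type == "num") {
    return(list(atoms = list(list(w = numeric(k), const = as.numeric(t0$value))),
                pos = pos + 1L))
  }
  if (t0$type == "name") {
    a <- atom_name(t0$value); p <- pos + 1L
    # name-minus-name difference, e.g. "b1 - b2 > 0.2"
    if (tk(p)$type == "-" && tk(p + 1L)$type == "name") {
      b <- atom_name(tk(p + 1L)$value)
      a$w <- a$w - b$w
      p <- p + 2L
    }
    return(list(atoms = list(a), pos = p))
  }
  stop("malformed hypothesis: unexpected token '", t0$value, "'")
}

parse_chain_rows <- function(toks, pos, coef_names) {
  terms <- list(); cmps <- character()
  tm <- parse_term(toks, pos, coef_names)
  terms[[1L]] <- tm$atoms; pos <- tm$pos
  repeat {
    if (pos > length(toks)) break
    op <- toks[[pos]]$type
    if (!op %in% c("<", ">", "=")) break
    pos <- pos + 1L
    tm <- parse_term(toks, pos, coef_names)
    terms[[length(terms) + 1L]] <- tm$atoms
    cmps <- c(cmps, op)
    pos <- tm$pos
  }
  if (length(cmps) == 0L)
    stop("hypothesis has no comparator ('<', '>' or '=')")
  RE <- NULL; rE <- numeric(); RI <- NULL; rI <- numeric()
  for (i in seq_along(cmps)) {
    for (a in terms[[i]]) for (b in terms[[i + 1L]]) {
      row <- a$w - b$w; rhs <- b$const - a$const; op <- cmps[i]
      if (op == "<") { row <- -row; rhs <- -rhs; op <- ">" }
      if (max(abs(row)) < 1e-12) {
        if (op == "=") {
          if (abs(rhs) > 1e-12)
            stop("inconsistent equality constraint (reduces to 0 = ", rhs, ")")
        } else if (rhs >= -1e-12) {
          stop("infeasible inequality constraint (reduces to 0 > ", rhs, ")")
        }
        next  # trivially satisfied
      }
      if (op == "=") { RE <- rbind(RE, row); rE <- c(rE, rhs) }
      else           { RI <- rbind(RI, row); rI <- c(rI, rhs) }
    }
  }
  list(R_E = RE, r_E = rE, R_I = RI, r_I = rI, pos = pos)
}

empty_rows <- function(k) matrix(numeric(), 0L, k)

new_constraint_system <- function(R_E, r_E, R_I, r_I, label, source, coef_names) {
  k <- length(coef_names)
  if (is.null(R_E)) { R_E <- empty_rows(k); r_E <- numeric() }
  if (is.null(R_I)) { R_I <- empty_rows(k); r_I <- numeric() }
  structure(list(R_E = unname(as.matrix(R_E)), r_E = as.numeric(r_E),
                 R_I = unname(as.matrix(R_I)), r_I = as.numeric(r_I),
                 label = label, source = source, coef_names = coef_names),
            class = "constraint_system")
}

# Drop linearly dependent equality rows; error if they are inconsistent.
reduce_equalities <- function(sys) {
  qE <- nrow(sys$R_E)
  if (qE <= 1L) return(sys)
  aug <- cbind(sys$R_E, sys$r_E)
  if (mat_rank(aug) > mat_rank(sys$R_E))
    stop("hypothesis '", sys$source, "' has inconsistent equality constraints")
  keep <- integer()
  for (i in seq_len(qE)) {
    cand <- sys$R_E[c(keep, i), , drop = FALSE]
    if (mat_rank(cand) == nrow(cand)) keep <- c(keep, i)
  }
  sys$R_E <- sys$R_E[keep, , drop = FALSE]
  sys$r_E <- sys$r_E[keep]
  sys
}

#' Parse hypothesis strings into constraint systems
#'
#' Parses the semicolon-separated constraint mini-language used throughout the
#' package (e.g. `"b1 > b2 > b3 > 0; b1 = b2 = b3 > 0"`, or grouped forms such
#' as `"beliefW > (stigma, feminist) = 0"`) into one constraint system
#' `R_E beta = r_E & R_I beta > r_I` per hypothesis. Chains attach adjacent
#' pairs only; `"<"` is normalised to `">"`; redundant equality rows are
#' dropped; redundant inequality rows produced by group expansion are kept
#' (rank handling downstream routes them to Monte Carlo). Every hypothesis is
#' checked for feasibility (a point satisfying the equalities and strictly
#' satisfying the inequalities must exist).
#'
#' @param spec a non-empty string of one or more hypotheses separated by `";"`.
#' @param coef_names character vector of coefficient names in the model.
#' @return A list of `"constraint_system"` objects with fields `R_E`, `r_E`,
#'   `R_I`, `r_I`, `label` and `source`.
#' @examples
#' parse_hypotheses("b1 > b2 > b3 > 0", c("b0", "b1", "b2", "b3"))[[1]]
#' @export
parse_hypotheses <- function(spec, coef_names) {
  if (!is.character(spec) || length(spec) != 1L || !nzchar(trimws(spec)))
    stop("spec must be a non-empty hypothesis string")
  parts <- strsplit(spec, ";", fixed = TRUE)[[1]]
  parts <- trimws(parts)
  parts <- parts[nzchar(parts)]
  if (length(parts) == 0L) stop("spec contains no hypotheses")
  out <- vector("list", length(parts))
  for (h in seq_along(parts)) {
    toks <- tokenize_hyp(parts[h])
    RE <- NULL; rE <- numeric(); RI <- NULL; rI <- numeric(); pos <- 1L
    repeat {
      ch <- parse_chain_rows(toks, pos, coef_names)
      RE <- rbind(RE, ch$R_E); rE <- c(rE, ch$r_E)
      RI <- rbind(RI, ch$R_I); rI <- c(rI, ch$r_I)
      pos <- ch$pos
      if (pos > length(toks)) break
      if (toks[[pos]]$type != "&")
        stop("malformed hypothesis near '", toks[[pos]]$value, "' in: ", parts[h])
      pos <- pos + 1L
    }
    sys <- new_constraint_system(RE, rE, RI, rI, paste0("H", h), parts[h], coef_names)
    if (nrow(sys$R_E) + nrow(sys$R_I) < 1L)
      stop("hypothesis '", parts[h], "' contains no constraints")
    sys <- reduce_equalities(sys)
    feas <- check_feasibility(sys)
    if (!feas$feasible)
      stop("hypothesis '", parts[h], "' is infeasible (no parameter value ",
           "satisfies the equalities and strictly satisfies the inequalities)")
    out[[h]] <- sys
  }
  out
}

#' Exploratory zero/positive/negative hypothesis triple
#'
#' Builds the three exploratory hypotheses for one coefficient: a negative, a
#' zero and a positive effect. The triple partitions the real line, so no
#' complement is added in exploratory mode.
#'
#' @param coef_name name of the coefficient to test.
#' @param coef_names all coefficient names in the model.
#' @return List of three `"constraint_system"` objects (`beta < 0`,
#'   `beta = 0`, `beta > 0`), with the exhaustiveness flag set as an attribute.
#' @export
exploratory_hypotheses <- function(coef_name, coef_names) {
  if (!coef_name %in% coef_names)
    stop("unknown coefficient '", coef_name, "'; valid names: ",
         paste(coef_names, collapse = ", "))
  k <- length(coef_names)
  e <- numeric(k); e[match(coef_name, coef_names)] <- 1
  nm <- coef_name
  out <- list(
    new_constraint_system(NULL, NULL, matrix(-e, 1L), 0, "H1",
                          paste0(nm, "<0"), coef_names),
    new_constraint_system(matrix(e, 1L), 0, NULL, NULL, "H2",
                          paste0(nm, "=0"), coef_names),
    new_constraint_system(NULL, NULL, matrix(e, 1L), 0, "H3",
                          paste0(nm, ">0"), coef_names))
  attr(out, "exhaustive") <- TRUE
  out
}

#' Feasibility of a constraint system
#'
#' Checks whether a point `beta*` exists with `R_E beta* = r_E` and
#' `R_I beta* > r_I` strictly. Equalities are solved in minimum-norm form; a
#' strictly interior point for the inequalities is then sought in the null
#' space of `R_E` by minimising squared hinge violations at a positive margin
#' (a convex program). Returns `FALSE` rather than raising; callers raise.
#'
#' @param sys a `"constraint_system"`.
#' @return List with elements `feasible` (logical) and `witness` (a feasible
#'   point, or `NULL`).
#' @export
check_feasibility <- function(sys) {
  k <- ncol(sys$R_E)
  qE <- nrow(sys$R_E); qI <- nrow(sys$R_I)
  if (qE > 0L) {
    beta0 <- drop(pinv(sys$R_E) %*% sys$r_E)
    if (max(abs(sys$R_E %*% beta0 - sys$r_E)) > 1e-8 * max(1, max(abs(sys$r_E))))
      return(list(feasible = FALSE, witness = NULL))
    N <- null_basis(sys$R_E, k)
  } else {
    beta0 <- numeric(k)
    N <- diag(k)
  }
  if (qI == 0L) return(list(feasible = TRUE, witness = beta0))
  A <- sys$R_I %*% N
  b <- drop(sys$r_I - sys$R_I %*% beta0)
  zero <- rowSums(abs(A)) < 1e-12
  if (any(zero & b >= -1e-12)) return(list(feasible = FALSE, witness = NULL))
  A <- A[!zero, , drop = FALSE]; b <- b[!zero]
  if (nrow(A) == 0L) return(list(feasible = TRUE, witness = beta0))
  if (ncol(A) == 0L) return(list(feasible = FALSE, witness = NULL))
  scale <- max(abs(b), 1)
  for (margin in scale * c(1, 1e-2, 1e-4)) {
    target <- b + margin
    z0 <- drop(pinv(A) %*% target)
    obj <- function(z) sum(pmax(target - A %*% z, 0)^2)
    gr <- function(z) drop(-2 * t(A) %*% pmax(target - A %*% z, 0))
    z <- if (obj(z0) < 1e-18) z0 else
      optim(z0, obj, gr, method = "BFGS",
            control = list(maxit = 1000L, reltol = 1e-15))$par
    if (max(b + margin / 2 - A %*% z) < 0)
      return(list(feasible = TRUE, witness = drop(beta0 + N %*% z)))
  }
  list(feasible = FALSE, witness = NULL)
}

# Canonical in-grammar rendering of one constraint row (at most two +/-1
# entries); used for the text round-trip.
render_row <- function(w, rhs, op, coef_names) {
  nz <- which(abs(w) > 1e-12)
  if (length(nz) == 1L && abs(abs(w[nz]) - 1) < 1e-12) {
    if (w[nz] > 0) return(paste0(coef_names[nz], op, format(rhs, digits = 15)))
    flip <- if (op == ">") "<" else op
    return(paste0(coef_names[nz], flip, format(-rhs, digits = 15)))
  }
  if (length(nz) == 2L && abs(w[nz[1]] + w[nz[2]]) < 1e-12 &&
      abs(abs(w[nz[1]]) - 1) < 1e-12) {
    pos <- nz[which(w[nz] > 0)]; neg <- nz[which(w[nz] < 0)]
    return(paste0(coef_names[pos], "-", coef_names[neg], op,
                  format(rhs, digits = 15)))
  }
  stop("constraint row has no canonical text form in the hypothesis grammar")
}

#' @export
format.constraint_system <- function(x, ...) {
  frags <- character()
  qE <- nrow(x$R_E); qI <- nrow(x$R_I)
  for (i in seq_len(qE))
    frags <- c(frags, render_row(x$R_E[i, ], x$r_E[i], "=", x$coef_names))
  for (i in seq_len(qI))
    frags <- c(frags, render_row(x$R_I[i, ], x$r_I[i], ">", x$coef_names))
  paste(frags, collapse = " & ")
}

#' @export
print.constraint_system <- function(x, ...) {
  cat(x$label, ": \"", x$source, "\"\n", sep = "")
  if (nrow(x$R_E)) {
    cat("  [R_E | r_E]:\n")
    print(cbind(x$R_E, x$r_E))
  }
  if (nrow(x$R_I)) {
    cat("  [R_I | r_I]:\n")
    print(cbind(x$R_I, x$r_I))
  }
  invisible(x)
}
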