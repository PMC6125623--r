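#' @title Pluggable LP/MILP solver backend
#'
#' @description Linear and mixed-integer linear programs are described by a
#' small backend-agnostic contract (objective, sparse constraint matrix with
#' row bounds, variable bounds, integrality) and solved in batches. The
#' default backend delegates to HiGHS through the SciPy installation found on
#' the PATH; batching amortises interpreter startup, which dominates the cost
#' of the small problems this package generates.
#'
#' @name solver-backend
NULL

.INF_SENTINEL <- 1e30

#' Construct an LP/MILP problem description
#'
#' @param obj numeric objective coefficient vector (one entry per variable).
#' @param A constraint matrix: a base or \pkg{Matrix} matrix, or a triplet
#'   list with elements `i`, `j`, `x`, `nrow` (1-based indices).
#' @param row_lb,row_ub constraint row bounds (use `-Inf`/`Inf` for one-sided
#'   rows; equality rows have `row_lb == row_ub`).
#' @param lb,ub variable bounds.
#' @param int_vars integer vector of 1-based indices of binary/integer
#'   variables.
#' @param maximize logical; maximize instead of minimize.
#' @param vars optional character vector of variable names (used to name the
#'   solution vector).
#' @param name optional problem label used in error messages.
#' @return an object of class `lp_problem`.
#' @keywords internal
lp_problem <- function(obj, A = NULL, row_lb = numeric(), row_ub = numeric(),
                       lb, ub, int_vars = integer(), maximize = FALSE,
                       vars = NULL, name = "") {
  nvar <- length(obj)
  stopifnot(length(lb) == nvar, length(ub) == nvar)
  trip <- as_triplets(A, nvar)
  stopifnot(length(row_lb) == trip$nrow, length(row_ub) == trip$nrow)
  structure(list(
    nvar = nvar, obj = as.numeric(obj), maximize = isTRUE(maximize),
    A = trip, row_lb = as.numeric(row_lb), row_ub = as.numeric(row_ub),
    lb = as.numeric(lb), ub = as.numeric(ub),
    int_vars = as.integer(int_vars), vars = vars, name = name
  ), class = "lp_problem")
}

as_triplets <- function(A, nvar) {
  if (is.null(A)) {
    return(list(i = integer(), j = integer(), x = numeric(), nrow = 0L))
  }
  if (is.list(A) && !is.null(A$nrow)) {
    return(list(i = as.integer(A$i), j = as.integer(A$j),
                x = as.numeric(A$x), nrow = as.integer(A$nrow)))
  }
  Am <- methods::as(methods::as(Matrix::Matrix(A, sparse = TRUE), "generalMatrix"),
                    "TsparseMatrix")
  stopifnot(ncol(Am) == nvar)
  list(i = Am@i + 1L, j = Am@j + 1L, x = Am@x, nrow = nrow(Am))
}

python_bin <- function() {
  opt <- getOption("carvenet.python", NULL)
  if (!is.null(opt)) return(opt)
  for (cand in c("python", "python3")) {
    p <- Sys.which(cand)
    if (nzchar(p)) return(unname(p))
  }
  stop("No python interpreter found on the PATH; the default solver backend ",
       "requires python with scipy (see ?solver-backend).")
}

solver_script <- function() {
  p <- system.file("python", "lp_solve.py", package = "carvenet")
  if (!nzchar(p)) stop("solver script not found; is carvenet installed?")
  p
}

encode_problem <- function(p) {
  num <- function(v) {
    v[v >= .INF_SENTINEL | is.infinite(v) & v > 0] <- .INF_SENTINEL
    v[v <= -.INF_SENTINEL | is.infinite(v) & v < 0] <- -.INF_SENTINEL
    v
  }
  list(
    nvar = p$nvar, obj = num(p$obj), maximize = p$maximize,
    A = list(i = p$A$i, j = p$A$j, x = p$A$x, nrow = p$A$nrow),
    row_lb = num(p$row_lb), row_ub = num(p$row_ub),
    lb = num(p$lb), ub = num(p$ub), int_vars = p$int_vars
  )
}

#' Solve a batch of LP/MILP problems
#'
#' @param problems a list of [lp_problem()] objects.
#' @param time_limit per-problem time limit in seconds.
#' @return a list with one element per problem: `status` (one of `"optimal"`,
#'   `"infeasible"`, `"unbounded"`, `"limit"`, `"error"`), and for optimal
#'   problems `objective` and the solution vector `x` (named when the problem
#'   carried variable names).
#' @keywords internal
solve_lp_batch <- function(problems, time_limit = 60) {
  stopifnot(is.list(problems))
  if (length(problems) == 0L) return(list())
  payload <- list(problems = lapply(problems, function(p) {
    enc <- encode_problem(p)
    enc$options <- list(time_limit = time_limit)
    enc
  }))
  infile <- tempfile(fileext = ".json")
  outfile <- tempfile(fileext = ".json")
  on.exit(unlink(c(infile, outfile)), add = TRUE)
  jsonlite::write_json(payload, infile, auto_unbox = TRUE, digits = NA)
  status <- system2(python_bin(), c(solver_script(), infile, outfile),
                    stdout = FALSE, stderr = "")
  if (!identical(status, 0L) || !file.exists(outfile)) {
    stop("solver backend failed (exit status ", status, ")")
  }
  res <- jsonlite::read_json(outfile, simplifyVector = TRUE)$results
  if (is.data.frame(res)) {
    res <- lapply(seq_len(nrow(res)), function(k) {
      r <- list(status = res$status[[k]])
      if (!is.null(res$objective)) r$objective <- res$objective[[k]]
      if (!is.null(res$x)) r$x <- res$x[[k]]
      if (!is.null(res$message)) r$message <- res$message[[k]]
      r
    })
  }
  stopifnot(length(res) == length(problems))
  Map(function(r, p) {
    if (identical(r$status, "optimal") && !is.null(p$vars)) {
      names(r$x) <- p$vars
    }
    r
  }, res, problems)
}

#' Solve a single LP/MILP problem
#' @inheritParams solve_lp_batch
#' @param problem an [lp_problem()].
#' @keywords internal
solve_lp <- function(problem, time_limit = 60) {
  solve_lp_batch(list(problem), time_limit = time_limit)[[1L]]
}
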