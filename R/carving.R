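#' @title Model carving
#' @description Carving converts the universal model into an organism model
#'   by solving a MILP that maximises the total score of active reactions
#'   while enforcing steady-state connectivity and a minimum growth rate:
#'
#'   maximise `s' (y_f + y_r)` subject to `S v = 0`,
#'   `-M y_r + eps y_f <= v <= -eps y_r + M y_f`, direction restrictions for
#'   irreversible reactions, `y_f + y_r <= 1` and `v_growth >= min_growth`.
#'
#'   Every active reaction is forced to carry at least `eps` flux in one
#'   simultaneous flux distribution, so the selected subnetwork is gapless by
#'   construction. The MILP is solved with all exchanges open (complete
#'   medium): carving is context independent and infers uptake capabilities
#'   from genetic evidence alone.
#' @name carving
NULL

#' Carving parameters
#'
#' @param epsilon minimum flux carried by an active reaction
#'   (default 0.001 mmol/gDW/h).
#' @param bigM maximum flux bound (default 100 mmol/gDW/h).
#' @param min_growth minimum growth rate (default 0.1 h^-1).
#' @param w_soft weight added to the objective by each soft constraint
#'   (default 1.0, on the normalized-score scale).
#' @param time_limit solver time limit per MILP, seconds.
#' @param feas_tol numerical slack accepted when checking the flux
#'   certificate against `epsilon` (solver integrality/feasibility noise).
#' @return a list of class `carve_params`.
#' @export
carve_params <- function(epsilon = 0.001, bigM = 100, min_growth = 0.1,
                         w_soft = 1.0, time_limit = 120, feas_tol = 1e-6) {
  stopifnot(epsilon > 0, epsilon < bigM, min_growth > 0)
  structure(list(epsilon = epsilon, bigM = bigM, min_growth = min_growth,
                 w_soft = w_soft, time_limit = time_limit,
                 feas_tol = feas_tol), class = "carve_params")
}

# Build the carving MILP for a given score vector. Variables are laid out as
# [v (n), y_f (n), y_r (n)]; impossible directions have their binaries fixed
# to zero through bounds.
carve_problem <- function(universe, svec, params, soft = NULL, hard = NULL) {
  m <- complete_medium(universe, params$bigM)
  n <- nrow(m$rxns)
  M <- params$bigM
  eps <- params$epsilon
  lb <- pmax(m$rxns$lb, -M)
  ub <- pmin(m$rxns$ub, M)
  if (!is.null(hard)) {
    for (rid in names(hard)) {
      k <- rxn_idx(m, rid)
      lb[k] <- max(-M, hard[[rid]][1])
      ub[k] <- min(M, hard[[rid]][2])
    }
  }
  gk <- rxn_idx(m, m$objective)
  lb[gk] <- max(lb[gk], params$min_growth)
  yf_ub <- as.numeric(ub > 0)
  yr_ub <- as.numeric(lb < 0)
  obj <- c(numeric(n), svec, svec)
  if (!is.null(soft)) {
    w <- params$w_soft
    for (rid in names(soft)) {
      k <- rxn_idx(m, rid)
      val <- soft[[rid]]
      if (val == 1) obj[n + k] <- obj[n + k] + w
      else if (val == -1) obj[2 * n + k] <- obj[2 * n + k] + w
      else if (val == 0) {
        obj[n + k] <- obj[n + k] - w
        obj[2 * n + k] <- obj[2 * n + k] - w
      } else stop("soft constraint values must be in {-1, 0, 1}")
    }
  }
  sk <- fba_skeleton(m)
  Sm <- methods::as(methods::as(sk$S, "generalMatrix"), "TsparseMatrix")
  ii <- Sm@i + 1L; jj <- Sm@j + 1L; xx <- Sm@x
  nrow0 <- sk$nrow
  # v - eps y_f + M y_r >= 0  (rows nrow0+1 .. nrow0+n)
  r1 <- nrow0 + seq_len(n)
  ii <- c(ii, r1, r1, r1)
  jj <- c(jj, seq_len(n), n + seq_len(n), 2 * n + seq_len(n))
  xx <- c(xx, rep(1, n), rep(-eps, n), rep(M, n))
  # v - M y_f + eps y_r <= 0  (rows nrow0+n+1 .. nrow0+2n)
  r2 <- nrow0 + n + seq_len(n)
  ii <- c(ii, r2, r2, r2)
  jj <- c(jj, seq_len(n), n + seq_len(n), 2 * n + seq_len(n))
  xx <- c(xx, rep(1, n), rep(-M, n), rep(eps, n))
  # y_f + y_r <= 1  (rows nrow0+2n+1 .. nrow0+3n)
  r3 <- nrow0 + 2 * n + seq_len(n)
  ii <- c(ii, r3, r3)
  jj <- c(jj, n + seq_len(n), 2 * n + seq_len(n))
  xx <- c(xx, rep(1, n), rep(1, n))
  row_lb <- c(numeric(nrow0), numeric(n), rep(-Inf, n), rep(-Inf, n))
  row_ub <- c(numeric(nrow0), rep(Inf, n), numeric(n), rep(1, n))
  lp_problem(
    obj = obj,
    A = list(i = ii, j = jj, x = xx, nrow = nrow0 + 3L * n),
    row_lb = row_lb, row_ub = row_ub,
    lb = c(lb, numeric(n), numeric(n)),
    ub = c(ub, yf_ub, yr_ub),
    int_vars = (n + 1L):(3L * n),
    maximize = TRUE,
    vars = c(m$rxns$id, paste0("yf.", m$rxns$id), paste0("yr.", m$rxns$id))
  )
}

carve_solution_from <- function(universe, res, svec, params) {
  n <- nrow(universe$rxns)
  v <- res$x[seq_len(n)]
  yf <- round(res$x[n + seq_len(n)])
  yr <- round(res$x[2 * n + seq_len(n)])
  kept <- universe$rxns$id[yf + yr > 0.5]
  names(v) <- names(yf) <- names(yr) <- universe$rxns$id
  structure(list(kept = kept, y_f = yf, y_r = yr, v = v,
                 objective = res$objective, scores = svec, params = params),
            class = "carve_solution")
}

#' @export
print.carve_solution <- function(x, ...) {
  cat("<carve_solution> ", length(x$kept), " reactions kept, objective ",
      format(x$objective, digits = 6), "\n", sep = "")
  invisible(x)
}

#' Carve an organism model out of the universe
#'
#' @param universe the universal `metabolic_model` (feasible at `min_growth`
#'   under the complete medium).
#' @param scores a `reaction_scores` table ([compute_reaction_scores()]);
#'   reactions absent from the table default to -1 (enzymatic/transport) or
#'   0.
#' @param params a [carve_params()] object.
#' @param soft optional soft constraints: named list/vector reaction id ->
#'   value in `{1, -1, 0}` (forward preferred / backward preferred / should
#'   not occur); each adds `w_soft` to the matching direction binary (or
#'   subtracts it from both for 0).
#' @param hard optional hard constraints: named list reaction id ->
#'   `c(vmin, vmax)`, overriding the flux bounds (may render the MILP
#'   infeasible).
#' @return a `carve_solution` with the kept reaction set, direction
#'   indicators `y_f`/`y_r`, the certificate flux vector `v` and the carved
#'   `model`.
#' @export
carve <- function(universe, scores, params = carve_params(), soft = NULL,
                  hard = NULL) {
  if (is.na(universe$objective)) stop("universe has no objective reaction")
  svec <- score_vector(scores, universe)
  prob <- carve_problem(universe, svec, params, soft = soft, hard = hard)
  res <- solve_lp(prob, time_limit = params$time_limit)
  if (!identical(res$status, "optimal")) {
    if (!is.null(hard)) {
      retry <- solve_lp(carve_problem(universe, svec, params, soft = soft),
                        time_limit = params$time_limit)
      if (identical(retry$status, "optimal")) {
        stop("carving MILP infeasible because of the hard constraints ",
             "(the problem is feasible without them)")
      }
    }
    stop("carving MILP not solved to optimality: ", res$status,
         " (is the universe growth-capable on the complete medium?)")
  }
  sol <- carve_solution_from(universe, res, svec, params)
  sol$model <- prune_to_model(universe, sol, scores)
  sol
}

#' Reduce the universe to the carved model
#'
#' Removes every reaction with both direction indicators at zero, then all
#' consequently orphaned metabolites (genes are implicit in the GPRs and
#' disappear with their reactions). Bounds are inherited from the universe;
#' organism-specific GPRs from the score table replace the universe GPRs on
#' scored reactions; the biomass objective is retained.
#'
#' @param universe the universal model.
#' @param solution a `carve_solution`.
#' @param scores optional `reaction_scores` carrying organism GPRs.
#' @return the carved `metabolic_model`.
#' @export
prune_to_model <- function(universe, solution, scores = NULL) {
  m <- keep_reactions(universe, solution$kept)
  if (!is.null(scores)) {
    k <- match(m$rxns$id, scores$reaction)
    hit <- which(!is.na(k) & scores$evidence[k])
    m$rxns$gpr[hit] <- scores$gpr[k[hit]]
  }
  m$id <- paste0(universe$id, "_carved")
  validate_model(m)
  m
}

#' Check the carve certificate
#'
#' Verifies that the certificate flux vector satisfies `S v = 0`, that every
#' kept reaction carries at least `epsilon` flux (up to solver feasibility
#' tolerance) in the direction of its indicator, and that growth meets
#' `min_growth`.
#'
#' @param universe the universal model.
#' @param solution a `carve_solution`.
#' @return `TRUE` invisibly; stops with a diagnostic otherwise.
#' @export
check_carve_certificate <- function(universe, solution) {
  params <- solution$params
  tol <- params$feas_tol
  S <- build_stoichiometric_matrix(universe)
  S <- S[!universe$mets$boundary, , drop = FALSE]
  resid <- as.numeric(S %*% solution$v)
  if (any(abs(resid) > 1e-6)) stop("certificate violates S v = 0")
  v_kept <- solution$v[solution$kept]
  if (any(abs(v_kept) < params$epsilon - tol)) {
    stop("kept reaction below epsilon flux: ",
         paste(names(v_kept)[abs(v_kept) < params$epsilon - tol], collapse = ", "))
  }
  if (solution$v[[universe$objective]] < params$min_growth - tol) {
    stop("certificate growth below min_growth")
  }
  dropped <- setdiff(names(solution$v), solution$kept)
  if (any(abs(solution$v[dropped]) > tol)) {
    stop("dropped reaction carries flux")
  }
  invisible(TRUE)
}

#' Read soft constraints (`reaction_id`, `value` in {-1, 0, 1})
#' @param path TSV file path.
#' @return named list suitable for [carve()]'s `soft` argument.
#' @export
read_soft_constraints_tsv <- function(path) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("reaction_id", "value") %in% names(tb)))
  if (!all(tb$value %in% c(-1, 0, 1))) {
    stop("soft constraint values must be in {-1, 0, 1}")
  }
  stats::setNames(as.list(tb$value), tb$reaction_id)
}

#' Read hard constraints (`reaction_id`, `lb`, `ub`)
#' @param path TSV file path.
#' @return named list suitable for [carve()]'s `hard` argument.
#' @export
read_hard_constraints_tsv <- function(path) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("reaction_id", "lb", "ub") %in% names(tb)))
  if (any(tb$lb > tb$ub)) stop("hard constraints must satisfy lb <= ub")
  stats::setNames(lapply(seq_len(nrow(tb)), function(k) c(tb$lb[k], tb$ub[k])),
                  tb$reaction_id)
}
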