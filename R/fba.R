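# Desk-scale flux balance analysis: a stoichiometric model is turned into
# the linear program max c.v s.t. S.v = 0, lb <= v <= ub, with a biomass
# reaction synthesised from a composition mapping and measured exchange
# rates applied as (by default) equality constraints. Solved with the
# package's own two-phase simplex (R/lp.R) after shifting reversible
# fluxes to non-negative variables.

#' Stoichiometric matrix of a reconstruction
#'
#' @param recon a reconstruction.
#' @return Metabolites x reactions matrix of signed coefficients.
#' @export
recon_smatrix <- function(recon) {
  stopifnot(inherits(recon, "reconstruction"))
  S <- matrix(0, length(recon$metabolites), length(recon$reactions),
              dimnames = list(recon$metabolites, names(recon$reactions)))
  for (r in recon$reactions) S[names(r$stoich), r$id] <- r$stoich
  S
}

#' Build a flux model with biomass objective and exchange constraints
#'
#' Appends a biomass reaction consuming the stated composition (positive
#' coefficients = amount drained per unit of growth), sets default bounds
#' (reversible reactions get a negative lower bound), and applies measured
#' exchange rates to named reactions either as fixed equalities (the
#' default, mirroring rates that were directly imposed) or as bounds.
#'
#' @param recon a reconstruction.
#' @param biomass named numeric vector: metabolite id -> drain coefficient
#'   (> 0). All components must exist in the reconstruction.
#' @param exchanges named list: reaction id -> a single rate (fixed when
#'   \code{exchange_mode = "equality"}, an upper bound otherwise) or a
#'   length-2 \code{c(lb, ub)}.
#' @param default_bound magnitude of the default flux bounds.
#' @param exchange_mode \code{"equality"} or \code{"bound"}.
#' @return A \code{"flux_model"}: stoichiometric matrix \code{S} (with the
#'   biomass column), \code{lb}, \code{ub}, \code{objective}.
#' @export
build_flux_model <- function(recon, biomass, exchanges = list(),
                             default_bound = 1000,
                             exchange_mode = c("equality", "bound")) {
  exchange_mode <- match.arg(exchange_mode)
  stopifnot(is.numeric(biomass), length(biomass) > 0, all(biomass > 0))
  missing_ids <- setdiff(names(biomass), recon$metabolites)
  if (length(missing_ids)) {
    stop("biomass components absent from the reconstruction: ",
         paste(missing_ids, collapse = ", "))
  }
  S <- recon_smatrix(recon)
  bm <- numeric(nrow(S)); names(bm) <- rownames(S)
  bm[names(biomass)] <- -biomass
  S <- cbind(S, biomass = bm)
  rev <- c(vapply(recon$reactions, `[[`, NA, "reversible"), FALSE)
  lb <- ifelse(rev, -default_bound, 0)
  ub <- rep(default_bound, ncol(S))
  names(lb) <- names(ub) <- colnames(S)
  for (rid in names(exchanges)) {
    if (!rid %in% colnames(S)) stop("unknown exchange reaction '", rid, "'")
    v <- exchanges[[rid]]
    if (length(v) == 2) {
      lb[rid] <- v[1]; ub[rid] <- v[2]
    } else if (exchange_mode == "equality") {
      lb[rid] <- ub[rid] <- v
    } else {
      ub[rid] <- v
    }
  }
  if (any(lb > ub)) stop("inconsistent bounds: lower exceeds upper")
  structure(list(S = S, lb = lb, ub = ub, objective = "biomass",
                 default_bound = default_bound),
            class = "flux_model")
}

#' Solve a flux model by linear programming
#'
#' Maximises the objective flux subject to steady state (S.v = 0) and the
#' flux bounds. Variables are shifted by their lower bounds so the LP has
#' non-negative variables, then solved with a self-contained two-phase
#' tableau simplex (Bland's rule); the returned point is re-validated
#' against every constraint before being reported optimal. Bounds
#' are finite by construction (\code{default_bound}); if the optimum rests
#' on a default-capped bound the solution is flagged as bound-limited,
#' the signature of an effectively unbounded objective.
#'
#' @param model a \code{\link{build_flux_model}} model (or any list with
#'   S, lb, ub, objective).
#' @param tol steady-state residual tolerance used for the reported check.
#' @return A \code{"flux_solution"}: \code{fluxes} (named vector),
#'   \code{objective} value, \code{status} ("optimal", "infeasible" or
#'   "unsolved"), \code{residual} = max |S.v|, and
#'   \code{bound_limited}.
#' @export
solve_fba <- function(model, tol = 1e-6) {
  S <- model$S; lb <- model$lb; ub <- model$ub
  n <- ncol(S)
  cc <- numeric(n); names(cc) <- colnames(S)
  cc[model$objective] <- 1
  infeasible <- structure(list(fluxes = NULL, objective = NA_real_,
                               status = "infeasible", residual = NA_real_,
                               bound_limited = NA),
                          class = "flux_solution")
  # eliminate zero-width (fixed) variables: the simplex mishandles
  # degenerate box constraints, so substitute them into the balance rhs
  free <- which(ub - lb > 0)
  v <- lb
  if (length(free) == 0) {
    if (max(abs(S %*% v)) > tol) return(infeasible)
  } else {
    Sf <- S[, free, drop = FALSE]
    rhs <- as.vector(-S %*% lb)
    res <- lp_solve_box(cc[free], Sf, rhs, (ub - lb)[free])
    if (res$status == "infeasible") return(infeasible)
    if (res$status != "optimal") {
      return(structure(list(fluxes = NULL, objective = NA_real_,
                            status = res$status, residual = NA_real_,
                            bound_limited = NA),
                       class = "flux_solution"))
    }
    v[free] <- res$x + lb[free]
  }
  names(v) <- colnames(S)
  # trust but verify: the claimed optimum must satisfy every constraint
  scale <- max(1, max(abs(v)))
  if (max(abs(S %*% v)) > tol * scale ||
      any(v < lb - 1e-8 * scale) || any(v > ub + 1e-8 * scale)) {
    return(infeasible)
  }
  at_cap <- any(abs(abs(v) - model$default_bound) < 1e-8 &
                  (abs(ub - model$default_bound) < 1e-8 |
                     abs(lb + model$default_bound) < 1e-8))
  structure(list(fluxes = v,
                 objective = sum(cc * v),
                 status = "optimal",
                 residual = max(abs(S %*% v)),
                 bound_limited = isTRUE(at_cap),
                 tol = tol),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("FBA solution:", x$status)
  if (x$status == "optimal") {
    cat(", objective =", signif(x$objective, 6),
        ", max |S.v| =", format(x$residual, digits = 3))
    if (isTRUE(x$bound_limited)) cat(" (bound-limited)")
  }
  cat("\n")
  invisible(x)
}
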