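# Calibration machinery: rmsd objective against partition datasets,
# bounded derivative-free optimisation of selected SSIP values and solvent
# constants, and a synthetic-data generator for parameter-recovery tests.
#
# Free parameters are addressed by reference strings into the registry:
#   solvent/<name>/<field>   e.g. solvent/hexane/c_alpha
#   class/<class>/<field>    e.g. class/ethers/c_beta2
#   group/<code>/<role>/<n>  e.g. group/[OX2H1]/acceptor/2  (the n-th
#                            acceptor value of that code, registry order)

#' Root-mean-square deviation
#'
#' The calibration objective: rmsd between calculated and experimental
#' free energies.
#'
#' @param calculated,experimental Numeric vectors of equal non-zero length
#'   (kJ/mol).
#' @return `sqrt(mean((calculated - experimental)^2))` in kJ/mol.
#' @examples
#' rmsd(c(1, 2), c(1, 2)) # 0
#' rmsd(c(3, 4), c(0, 0)) # sqrt(12.5)
#' @export
rmsd <- function(calculated, experimental) {
  if (length(calculated) != length(experimental) || length(calculated) == 0L) {
    stop("'calculated' and 'experimental' must have equal non-zero length",
         call. = FALSE)
  }
  sqrt(mean((calculated - experimental)^2))
}

#' Construct a partition dataset
#'
#' @param solute,smiles,solvent_from,solvent_to,dg_kjmol,source Record
#'   columns; `source` defaults to `"unknown"`.
#' @return A `partition_dataset` data frame. Duplicate
#'   (solute, solvent_from, solvent_to) keys or non-finite free energies
#'   are rejected.
#' @export
partition_dataset <- function(solute, smiles, solvent_from, solvent_to,
                              dg_kjmol, source = "unknown") {
  d <- data.frame(solute = solute, smiles = smiles,
                  solvent_from = solvent_from, solvent_to = solvent_to,
                  dg_kjmol = dg_kjmol, source = source,
                  stringsAsFactors = FALSE)
  if (!all(is.finite(d$dg_kjmol))) {
    stop("all experimental free energies must be finite", call. = FALSE)
  }
  key <- paste(d$solute, d$solvent_from, d$solvent_to, sep = "|")
  if (anyDuplicated(key)) {
    stop("duplicate (solute, solvent pair) records: ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  }
  class(d) <- c("partition_dataset", "data.frame")
  d
}

#' Specify a calibration run
#'
#' @param free Character vector of parameter references to optimise (see
#'   file header notation), e.g. `"solvent/hexane/c_alpha"`.
#' @param lower,upper Optional named bound vectors (defaults -20/20 kJ/mol
#'   for constants, 0.1/8 for polarity parameters).
#' @param frozen Character vector of references that must stay fixed
#'   (checked to be disjoint from `free`).
#' @param tol Convergence tolerance on the rmsd (kJ/mol).
#' @param max_iter Maximum number of coordinate-descent sweeps.
#' @param seed Integer seed (recorded for reproducibility).
#' @return A `fit_spec` object.
#' @export
fit_spec <- function(free, lower = NULL, upper = NULL, frozen = character(),
                     tol = 1e-4, max_iter = 500L, seed = 1L) {
  stopifnot(is.character(free))
  if (length(intersect(free, frozen))) {
    stop("free and frozen parameter sets overlap: ",
         paste(intersect(free, frozen), collapse = ", "), call. = FALSE)
  }
  if (any(grepl("/count", free))) {
    stop("SSIP counts are integers fixed by the assignment rules and ",
         "cannot be free parameters", call. = FALSE)
  }
  structure(list(free = free, lower = lower, upper = upper, frozen = frozen,
                 tol = tol, max_iter = as.integer(max_iter),
                 seed = as.integer(seed)),
            class = "fit_spec")
}

# ---- internal: mutable registry view -------------------------------------

.fit_view <- function() {
  reg <- .ssip_registry()
  list(simple = reg$simple, polar = reg$polar, groups = reg$groups,
       pi_faces = reg$pi_faces)
}

.split_ref <- function(ref) strsplit(ref, "/", fixed = TRUE)[[1]]

.get_ref <- function(view, ref) {
  p <- .split_ref(ref)
  if (p[1] == "solvent") {
    v <- view$simple[[p[2]]][[p[3]]]
    if (is.null(v)) stop("unknown parameter reference: ", ref, call. = FALSE)
    return(v)
  }
  if (p[1] == "class") {
    v <- view$polar[[p[2]]][[p[3]]]
    if (is.null(v)) stop("unknown parameter reference: ", ref, call. = FALSE)
    return(v)
  }
  if (p[1] == "group") {
    g <- view$groups
    rows <- which(g$code == p[2] & g$role == p[3])
    slot <- as.integer(p[4])
    if (!length(rows) || is.na(slot) || slot > length(rows)) {
      stop("unknown parameter reference: ", ref, call. = FALSE)
    }
    return(g$value[rows[slot]])
  }
  stop("unknown parameter reference: ", ref, call. = FALSE)
}

.set_ref <- function(view, ref, value) {
  p <- .split_ref(ref)
  if (p[1] == "solvent") {
    view$simple[[p[2]]][[p[3]]] <- value
  } else if (p[1] == "class") {
    view$polar[[p[2]]][[p[3]]] <- value
  } else if (p[1] == "group") {
    rows <- which(view$groups$code == p[2] & view$groups$role == p[3])
    view$groups$value[rows[as.integer(p[4])]] <- value
  }
  view
}

.default_bounds <- function(refs) {
  is_polarity <- grepl("(alpha_s|beta_s|/donor/|/acceptor/)", refs)
  list(lower = ifelse(is_polarity, 0.05, -20),
       upper = ifelse(is_polarity, 8, 20))
}

# ---- internal: fast prediction context -----------------------------------

# per-solute templates: integer indices into the groups value column for
# donor/acceptor sites (with multiplicity) plus fixed ring-centre values
.fit_solute_context <- function(smiles, groups, pi_faces) {
  graph <- parse_structure(smiles)
  codes <- assign_atom_codes(graph)
  a_idx <- integer(0); b_idx <- integer(0); ring_beta <- numeric(0)
  for (code in codes) {
    rows <- which(groups$code == code & groups$role %in% c("donor", "acceptor"))
    for (r in rows) {
      rep_r <- rep(r, groups$count[r])
      if (groups$role[r] == "donor") a_idx <- c(a_idx, rep_r)
      else b_idx <- c(b_idx, rep_r)
    }
  }
  if (length(graph$rings6)) {
    for (ring in graph$rings6) {
      n_alkyl <- sum(codes[ring] == "[c;alkyl]")
      hit <- match(n_alkyl, pi_faces$n_alkyl)
      if (is.na(hit)) stop("uncalibrated aromatic ring in ", smiles,
                           call. = FALSE)
      ring_beta <- c(ring_beta, rep(pi_faces$beta[hit], 2L))
    }
  }
  list(alpha_idx = a_idx, beta_idx = b_idx, ring_beta = ring_beta)
}

.fit_member_solvent <- function(name, view) {
  reg <- .ssip_registry()
  key <- .resolve_solvent_name(name, reg)
  if (key %in% names(view$simple)) return(view$simple[[key]])
  m <- reg$members[tolower(reg$members$member) == key, , drop = FALSE]
  if (nrow(m) != 1L) stop("unknown solvent in dataset: ", name, call. = FALSE)
  sol <- view$polar[[m$class]]
  sol$member <- m$member
  fr <- .member_site_fractions(m$member, m$smiles, reg)
  sol[names(fr)] <- fr
  sol
}

.predict_dg_star <- function(alphas, betas, solvent, rt) {
  if (inherits(solvent, "simple_solvent")) {
    s <- sum(-alphas * solvent$beta_s - solvent$c_beta) +
      sum(-solvent$alpha_s * betas - solvent$c_alpha)
  } else {
    k1 <- exp((alphas * solvent$beta_s1 + solvent$c_beta1) / rt)
    k2 <- exp((alphas * solvent$beta_s2 + solvent$c_beta2) / rt)
    da <- -rt * log(solvent$f_beta1 * k1 + solvent$f_beta2 * k2)
    j1 <- exp((solvent$alpha_s1 * betas + solvent$c_alpha1) / rt)
    j2 <- if (solvent$f_alpha2 == 0) 0 else
      exp((solvent$alpha_s2 * betas + solvent$c_alpha2) / rt)
    db <- -rt * log(solvent$f_alpha1 * j1 + solvent$f_alpha2 * j2)
    s <- sum(da) + sum(db)
  }
  s - solvent$c0
}

.fit_context <- function(dataset, constants) {
  reg <- .ssip_registry()
  solutes <- unique(dataset[, c("solute", "smiles")])
  ctx <- lapply(seq_len(nrow(solutes)), function(i) {
    .fit_solute_context(solutes$smiles[i], reg$groups, reg$pi_faces)
  })
  names(ctx) <- solutes$solute
  solvent_names <- unique(c(dataset$solvent_from, dataset$solvent_to))
  list(solute_ctx = ctx, solvent_names = solvent_names,
       rt = rt_kj(constants))
}

.fit_predict <- function(dataset, view, ctx) {
  solvents <- lapply(ctx$solvent_names, .fit_member_solvent, view = view)
  names(solvents) <- ctx$solvent_names
  gv <- view$groups$value
  vapply(seq_len(nrow(dataset)), function(k) {
    sc <- ctx$solute_ctx[[dataset$solute[k]]]
    alphas <- gv[sc$alpha_idx]
    betas <- c(gv[sc$beta_idx], sc$ring_beta)
    .predict_dg_star(alphas, betas, solvents[[dataset$solvent_to[k]]], ctx$rt) -
      .predict_dg_star(alphas, betas, solvents[[dataset$solvent_from[k]]],
                       ctx$rt)
  }, numeric(1))
}

# ---- fitting -------------------------------------------------------------

#' Calibrate SSIP values and solvent constants against partition data
#'
#' Minimises the rmsd between calculated and experimental transfer free
#' energies over the selected free parameters, holding everything else at
#' the shipped registry values. The optimiser is deliberately simple and
#' derivative-free: cyclic coordinate descent with a shrinking step,
#' followed by a Nelder-Mead polish, both respecting box bounds. Free
#' parameters whose perturbation leaves the objective unchanged (zero
#' sensitivity, i.e. not constrained by the dataset) are frozen with a
#' warning instead of drifting. The shipped registry is never modified;
#' the result carries the fitted values.
#'
#' @param dataset A [partition_dataset()] (or data frame with the same
#'   columns).
#' @param spec A [fit_spec()].
#' @param constants A [model_constants()] object.
#' @return A `fit_result`: fitted parameter values (`par`), `rmsd_initial`,
#'   `rmsd_final`, per-record `residuals` (calculated - experimental),
#'   `trace` of the rmsd across sweeps, and `frozen` (references dropped
#'   for lack of sensitivity).
#' @export
fit_parameters <- function(dataset, spec, constants = model_constants()) {
  stopifnot(inherits(spec, "fit_spec"))
  dataset <- as.data.frame(dataset)
  ctx <- .fit_context(dataset, constants)
  view0 <- .fit_view()
  set.seed(spec$seed)

  theta0 <- vapply(spec$free, function(r) .get_ref(view0, r), numeric(1))
  obj <- function(theta) {
    view <- view0
    for (i in seq_along(theta)) view <- .set_ref(view, spec$free[i], theta[i])
    pred <- .fit_predict(dataset, view, ctx)
    if (!all(is.finite(pred))) {
      stop("non-finite objective at parameters: ",
           paste(sprintf("%s=%.4g", spec$free, theta), collapse = ", "),
           call. = FALSE)
    }
    rmsd(pred, dataset$dg_kjmol)
  }

  r0 <- obj(theta0)

  # identifiability guard: freeze parameters the dataset cannot see
  frozen <- character(0)
  if (length(theta0)) {
    sens <- vapply(seq_along(theta0), function(i) {
      th <- theta0; th[i] <- th[i] + 1e-3
      abs(obj(th) - r0)
    }, numeric(1))
    dead <- sens == 0
    if (any(dead)) {
      frozen <- spec$free[dead]
      warning("parameter(s) with zero sensitivity frozen: ",
              paste(frozen, collapse = ", "), call. = FALSE)
    }
  }
  active <- setdiff(spec$free, frozen)

  par <- theta0
  trace <- r0
  if (length(active)) {
    ai <- match(active, spec$free)
    bounds <- .default_bounds(active)
    lower <- bounds$lower; upper <- bounds$upper
    if (!is.null(spec$lower)) {
      hit <- match(names(spec$lower), active)
      lower[hit[!is.na(hit)]] <- spec$lower[!is.na(hit)]
    }
    if (!is.null(spec$upper)) {
      hit <- match(names(spec$upper), active)
      upper[hit[!is.na(hit)]] <- spec$upper[!is.na(hit)]
    }

    step <- rep(0.5, length(active))
    best <- r0
    for (sweep in seq_len(spec$max_iter)) {
      improved <- FALSE
      for (j in seq_along(active)) {
        for (dir in c(1, -1)) {
          cand <- par
          cand[ai[j]] <- min(max(par[ai[j]] + dir * step[j], lower[j]),
                             upper[j])
          if (cand[ai[j]] == par[ai[j]]) next
          rc <- obj(cand)
          if (rc < best - 1e-15) {
            par <- cand; best <- rc; improved <- TRUE
            break
          }
        }
      }
      trace <- c(trace, best)
      if (!improved) {
        if (all(step < spec$tol)) break
        step <- step / 2
      }
      if (length(trace) > 3 &&
          abs(trace[length(trace) - 1] - best) < spec$tol &&
          all(step < spec$tol)) break
    }

    # simplex polish on the active coordinates (bounds enforced by clamping;
    # Brent for the one-dimensional case)
    polish <- function(th_active) {
      th <- par
      th[ai] <- pmin(pmax(th_active, lower), upper)
      obj(th)
    }
    opt <- if (length(active) == 1L) {
      stats::optim(par[ai], polish, method = "Brent", lower = lower,
                   upper = upper)
    } else {
      stats::optim(par[ai], polish, method = "Nelder-Mead",
                   control = list(reltol = 1e-12, maxit = 2000L))
    }
    if (opt$value < best) {
      par[ai] <- pmin(pmax(opt$par, lower), upper)
      best <- opt$value
    }
    trace <- c(trace, best)
  }

  view <- view0
  for (i in seq_along(par)) view <- .set_ref(view, spec$free[i], par[i])
  pred <- .fit_predict(dataset, view, ctx)
  final <- rmsd(pred, dataset$dg_kjmol)

  structure(
    list(par = par, rmsd_initial = r0, rmsd_final = final,
         residuals = pred - dataset$dg_kjmol, trace = trace,
         frozen = frozen, spec = spec, n = nrow(dataset)),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("SSIP calibration: %d records, rmsd %.4f -> %.4f kJ/mol\n",
              x$n, x$rmsd_initial, x$rmsd_final))
  if (length(x$par)) {
    for (i in seq_along(x$par)) {
      cat(sprintf("  %-35s = %8.4f%s\n", names(x$par)[i], x$par[i],
                  if (names(x$par)[i] %in% x$frozen) "  [frozen]" else ""))
    }
  }
  invisible(x)
}

#' Simulate a synthetic partition dataset from the shipped model
#'
#' Generates transfer free-energy records whose true values are the current
#' model predictions, optionally perturbed by i.i.d. Gaussian noise. Used
#' for parameter-recovery testing of [fit_parameters()].
#'
#' @param solutes Named character vector of SMILES (names become solute
#'   ids; unnamed vectors use the SMILES as id).
#' @param solvent_pairs Two-column data frame (`from`, `to`) of solvent
#'   names, or a character vector of destination solvents each paired with
#'   `reference`.
#' @param noise_sd Standard deviation of the added Gaussian noise (kJ/mol).
#' @param seed Integer seed; identical seeds give identical datasets.
#' @param reference Source solvent used when `solvent_pairs` is a plain
#'   character vector. Default "water".
#' @param overrides Optional named numeric vector of parameter references
#'   (same notation as [fit_spec()]) defining the generating parameter
#'   values, for parameter-recovery experiments. The registry itself is
#'   untouched.
#' @param constants A [model_constants()] object.
#' @return A [partition_dataset()].
#' @export
simulate_partition_dataset <- function(solutes, solvent_pairs, noise_sd = 0,
                                       seed = 1L, reference = "water",
                                       overrides = NULL,
                                       constants = model_constants()) {
  stopifnot(noise_sd >= 0)
  if (is.character(solvent_pairs)) {
    solvent_pairs <- data.frame(from = reference, to = solvent_pairs)
  }
  ids <- if (is.null(names(solutes))) solutes else names(solutes)
  grid <- expand.grid(si = seq_along(solutes),
                      pi = seq_len(nrow(solvent_pairs)))
  d <- data.frame(
    solute = ids[grid$si], smiles = unname(solutes[grid$si]),
    solvent_from = solvent_pairs$from[grid$pi],
    solvent_to = solvent_pairs$to[grid$pi],
    stringsAsFactors = FALSE
  )
  ctx <- .fit_context(d, constants)
  view <- .fit_view()
  if (!is.null(overrides)) {
    for (i in seq_along(overrides)) {
      view <- .set_ref(view, names(overrides)[i], overrides[[i]])
    }
  }
  dg <- .fit_predict(d, view, ctx)
  set.seed(seed)
  if (noise_sd > 0) dg <- dg + stats::rnorm(length(dg), 0, noise_sd)
  partition_dataset(d$solute, d$smiles, d$solvent_from, d$solvent_to, dg,
                    source = "synthetic")
}
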