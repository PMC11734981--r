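#' @importFrom stats integrate
#' @importFrom utils modifyList write.csv
NULL

# Phase ordering used everywhere in the package: healthy cells, cancer cells,
# young vessels, mature vessels, interstitial fluid.
PHASES <- c("h", "c", "yv", "mv", "int")
CHEMICALS <- c("c", "g", "a", "w")

.param_groups <- c(
  "cell_kinetics", "vascular", "mechanics", "chemotaxis", "oxygen", "vegf",
  "bevacizumab", "docetaxel", "radiotherapy", "scales"
)

#' Path of the bundled default parameter file
#'
#' The package ships one fully resolved dimensionless parameter set.  The
#' radiotherapy and radiosensitization blocks carry the published values
#' (strength of radiotherapy 0.23, kill half-life parameter 0.5, first
#' fraction at t = 80, daily fractions, sensitization multipliers 2 with
#' oxygen-mode strength 0.11).  The therapy-free, drag, diffusivity and drug
#' constants are a package-own calibration: they are pinned so that the
#' homeostatic tissue state (see [initial_state()]) is a fixed point of the
#' cell, oxygen and VEGF kinetics, and otherwise chosen at physiologically
#' sensible orders of magnitude (see the methods vignette).
#'
#' @return Path to the YAML file inside the installed package.
#' @export
default_parameter_file <- function() {
  system.file("extdata", "default_parameters.yaml", package = "crtsim",
              mustWork = TRUE)
}

#' Load and validate a model parameter set
#'
#' Reads a structured YAML configuration and merges it over the bundled
#' defaults.  Keys are grouped by subsystem (`cell_kinetics`, `vascular`,
#' `mechanics`, `chemotaxis`, `oxygen`, `vegf`, `bevacizumab`, `docetaxel`,
#' `radiotherapy`, `scales`); unknown groups or keys are rejected so typos
#' cannot silently fall back to defaults.  A parameter explicitly set to the
#' string `"unresolved"` marks a placeholder; loading such a file fails with
#' an error naming the missing symbol rather than guessing a value.
#'
#' @param config Either `NULL` (pure defaults), a path to a YAML file, or a
#'   named list of group -> key -> value overrides.
#' @return An object of class `crtsim_params`: a named list of parameter
#'   groups, each a named list of numeric (or logical/character) scalars,
#'   except `mechanics$d_ij` which is a symmetric 5x5 drag matrix.
#' @examples
#' p <- load_parameters()
#' p$radiotherapy$k_rad   # 0.23
#' p2 <- load_parameters(list(radiotherapy = list(N_rad = 15)))
#' @export
load_parameters <- function(config = NULL) {
  defaults <- yaml::read_yaml(default_parameter_file())
  over <- if (is.null(config)) {
    list()
  } else if (is.character(config) && length(config) == 1L) {
    yaml::read_yaml(config)
  } else if (is.list(config)) {
    config
  } else {
    stop("`config` must be NULL, a file path, or a named list", call. = FALSE)
  }

  bad_groups <- setdiff(names(over), .param_groups)
  if (length(bad_groups)) {
    stop("unknown parameter group(s): ", paste(bad_groups, collapse = ", "),
         call. = FALSE)
  }
  for (g in names(over)) {
    bad <- setdiff(names(over[[g]]), names(defaults[[g]]))
    if (length(bad)) {
      stop("unknown parameter(s) in group '", g, "': ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    defaults[[g]] <- utils::modifyList(defaults[[g]], over[[g]])
  }

  unresolved <- character(0)
  for (g in .param_groups) {
    vals <- defaults[[g]]
    for (k in names(vals)) {
      if (identical(vals[[k]], "unresolved")) {
        unresolved <- c(unresolved, paste0(g, "$", k))
      }
    }
  }
  if (length(unresolved)) {
    stop("parameter unresolved: ", paste(unresolved, collapse = ", "),
         "; supply explicit values before running a simulation",
         call. = FALSE)
  }

  p <- defaults
  p$mechanics$d_ij <- .build_drag_matrix(p$mechanics$d_ij)
  class(p) <- "crtsim_params"
  validate_parameters(p)
  p
}

# The drag table is stored in YAML as pairwise entries "h_c: value" etc.;
# expand to the symmetric zero-diagonal matrix used by the momentum solver.
.build_drag_matrix <- function(tbl) {
  if (is.matrix(tbl)) return(tbl)
  d <- matrix(0, 5, 5, dimnames = list(PHASES, PHASES))
  for (nm in names(tbl)) {
    ij <- strsplit(nm, "_", fixed = TRUE)[[1]]
    if (length(ij) != 2L || !all(ij %in% PHASES)) {
      stop("malformed drag pair name: ", nm, call. = FALSE)
    }
    d[ij[1], ij[2]] <- tbl[[nm]]
    d[ij[2], ij[1]] <- tbl[[nm]]
  }
  d
}

.flatten_drag_matrix <- function(d) {
  out <- list()
  for (i in 1:4) for (j in (i + 1):5) {
    out[[paste(PHASES[i], PHASES[j], sep = "_")]] <- d[i, j]
  }
  out
}

#' Validate a parameter set
#'
#' Checks the structural invariants of the model constants: non-negativity of
#' rates, diffusivities and steepness parameters, `0 < theta_star < 1`,
#' `c_c1 > c_c2` (starvation raises the death rate), symmetry and zero
#' diagonal of the drag table, the mechanical ordering of mature versus young
#' vessels (`p_crit_mv > p_crit_yv`, `k_occ_mv < k_occ_yv`), and a known
#' radiosensitization mode.
#'
#' @param p A `crtsim_params` object.
#' @return `p`, invisibly; stops with a validation error otherwise.
#' @export
validate_parameters <- function(p) {
  stopifnot(inherits(p, "crtsim_params"))
  nonneg <- c(
    p$cell_kinetics[c("k_m_h", "k_m_c", "k_d_h", "k_d_c", "c_p", "c_c1", "c_c2")],
    p$vascular[c("k_ang", "eps", "k_occ_yv", "k_occ_mv", "k_mat_ves",
                 "k_g1", "k_g2", "m", "nu")],
    p$oxygen[c("D_c", "k_rep", "c_v", "k_c_h", "k_c_c", "k_cm_h", "k_cm_c")],
    p$vegf[c("D_g", "k_sec", "omega", "c_a", "k_cang", "k_dg")],
    p$bevacizumab[c("D_a", "k_rep_a", "k_d_a", "k_n_a", "a_50", "k_cap_yv",
                    "k_ap_yv", "k_n_g", "a_inj", "k_el_a")],
    p$docetaxel[c("D_w", "k_rep_w", "k_d_w", "k_cn_h", "k_cn_c", "w_m",
                  "l_cr", "k_ap_h", "k_ap_c", "w_inj", "k_el_w")],
    p$radiotherapy[c("k_rad", "r_t", "xi_doc", "k_rad_ox", "xi_ox")],
    p$mechanics["mu"]
  )
  bad <- names(nonneg)[vapply(nonneg, function(x) !is.numeric(x) || x < 0,
                              logical(1))]
  if (length(bad)) {
    stop("validation error: negative or non-numeric parameter(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  for (h in c(p$vascular$h_occ, p$docetaxel$h_d, p$radiotherapy$h_s)) {
    if (!is.numeric(h) || h <= 0) {
      stop("validation error: Heaviside steepness parameters must be > 0",
           call. = FALSE)
    }
  }
  ts <- p$mechanics$theta_star
  if (!(ts > 0 && ts < 1)) {
    stop("validation error: theta_star must lie in (0, 1)", call. = FALSE)
  }
  if (!(p$cell_kinetics$c_c1 > p$cell_kinetics$c_c2)) {
    stop("validation error: c_c1 must exceed c_c2", call. = FALSE)
  }
  d <- p$mechanics$d_ij
  if (!isTRUE(all.equal(d, t(d))) || any(diag(d) != 0) || any(d < 0)) {
    stop("validation error: drag table d_ij must be symmetric, non-negative, ",
         "with zero diagonal", call. = FALSE)
  }
  if (!(p$vascular$p_crit_mv > p$vascular$p_crit_yv)) {
    stop("validation error: p_crit_mv must exceed p_crit_yv", call. = FALSE)
  }
  if (!(p$vascular$k_occ_mv < p$vascular$k_occ_yv)) {
    stop("validation error: k_occ_mv must be below k_occ_yv", call. = FALSE)
  }
  if (!(p$radiotherapy$sensitization_mode %in% c("none", "docetaxel", "oxygen"))) {
    stop("validation error: sensitization_mode must be one of ",
         "'none', 'docetaxel', 'oxygen'", call. = FALSE)
  }
  for (nm in c("N_rad", "Tp_rad")) {
    if (p$radiotherapy[[nm]] < 0) {
      stop("validation error: ", nm, " must be non-negative", call. = FALSE)
    }
  }
  if (p$bevacizumab$T_bev < 0 || p$docetaxel$T_doc < 0) {
    stop("validation error: injection periods must be non-negative",
         call. = FALSE)
  }
  invisible(p)
}

#' Serialize a parameter set to YAML
#'
#' Inverse of [load_parameters()]: `load_parameters(write_parameters(p, f))`
#' reproduces `p` for any valid parameter set.
#'
#' @param p A `crtsim_params` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(p, path) {
  stopifnot(inherits(p, "crtsim_params"))
  out <- unclass(p)
  out$mechanics$d_ij <- .flatten_drag_matrix(p$mechanics$d_ij)
  yaml::write_yaml(out, path, precision = 15L)
  invisible(path)
}

#' Build the therapy schedule from a parameter set
#'
#' Radiation fraction start times follow the arithmetic progression
#' `t_i = (i-1) * Tp_rad + t0_rad` for `i = 1..N_rad`.  When
#' `radiotherapy$weekend_breaks` is `TRUE` the fractions instead run on a
#' 5-days-on / 2-days-off calendar starting at `t0_rad`
#' (`t_i = t0_rad + (i-1) + 2*floor((i-1)/5)` for daily fractions).
#' Drug injections are arithmetic with periods `T_bev` and `T_doc`.
#'
#' @param params A `crtsim_params` object.
#' @param rt_on,bev_on,doc_on Logical flags enabling each agent; a disabled
#'   agent gets an empty schedule.
#' @return An object of class `crtsim_protocol` with components
#'   `radiation_times`, `bev_times`, `doc_times` and the on/off flags.
#' @examples
#' pr <- build_protocol(load_parameters())
#' head(pr$radiation_times)  # 80 81 82 ...
#' @export
build_protocol <- function(params, rt_on = TRUE, bev_on = TRUE, doc_on = TRUE) {
  stopifnot(inherits(params, "crtsim_params"))
  rt <- params$radiotherapy
  if (rt$Tp_rad < 0 || params$bevacizumab$T_bev < 0 || params$docetaxel$T_doc < 0) {
    stop("validation error: negative schedule period", call. = FALSE)
  }
  rad_times <- if (!rt_on || rt$N_rad == 0) {
    numeric(0)
  } else if (isTRUE(rt$weekend_breaks)) {
    i <- seq_len(rt$N_rad) - 1
    # business-day calendar: blocks of 5 treatment days separated by 2-day gaps
    rt$t0_rad + (i + 2 * (i %/% 5)) * rt$Tp_rad
  } else {
    rt$t0_rad + (seq_len(rt$N_rad) - 1) * rt$Tp_rad
  }
  bev <- params$bevacizumab
  doc <- params$docetaxel
  bev_times <- if (!bev_on || bev$N_bev == 0) numeric(0) else
    bev$t_inj1_bev + (seq_len(bev$N_bev) - 1) * bev$T_bev
  doc_times <- if (!doc_on || doc$N_doc == 0) numeric(0) else
    doc$t_inj1_doc + (seq_len(doc$N_doc) - 1) * doc$T_doc
  for (tv in list(rad_times, bev_times, doc_times)) {
    if (length(tv) > 1 && any(diff(tv) <= 0)) {
      stop("validation error: schedule times must be strictly increasing",
           call. = FALSE)
    }
  }
  structure(
    list(radiation_times = rad_times, bev_times = bev_times,
         doc_times = doc_times,
         rt_on = rt_on && length(rad_times) > 0,
         bev_on = bev_on && length(bev_times) > 0,
         doc_on = doc_on && length(doc_times) > 0),
    class = "crtsim_protocol"
  )
}

#' Initial tissue state: homeostasis plus a cancerous seed
#'
#' Builds the simulation state at `t = 0`: a homeostatic host tissue
#' (healthy cells 0.6, mature vessels 0.015, young vessels 0.002,
#' interstitial fluid 0.383, oxygen 0.25, VEGF 6e-4, drugs 0) with a
#' cancer seed `theta_c(r) = 0.05 cos^2(pi r / 2)` for `r <= R_seed` carved
#' out of the healthy-cell fraction, so the phases sum to one everywhere.
#' All velocities and pressures start at zero.
#'
#' @param grid A grid from [build_grid()].
#' @param params A `crtsim_params` object.
#' @return An object of class `crtsim_state` with fields `theta` (n x 5
#'   matrix, columns `h, c, yv, mv, int`), `chem` (n x 4 matrix, columns
#'   `c, g, a, w`), `u` ((n+1) x 5 matrix of face velocities), `p_int`
#'   (length-n vector) and `time`.
#' @export
initial_state <- function(grid, params) {
  stopifnot(inherits(grid, "crtsim_grid"), inherits(params, "crtsim_params"))
  r <- grid$cell_centers
  n <- length(r)
  R_seed <- params$scales$R_seed
  theta_c <- ifelse(r <= R_seed, 0.05 * cos(pi * r / 2)^2, 0)
  theta <- cbind(
    h = 0.6 - theta_c,
    c = theta_c,
    yv = rep(0.002, n),
    mv = rep(0.015, n),
    int = rep(0.383, n)
  )
  chem <- cbind(c = rep(0.25, n), g = rep(6e-4, n),
                a = rep(0, n), w = rep(0, n))
  structure(
    list(theta = theta, chem = chem,
         u = matrix(0, n + 1, 5, dimnames = list(NULL, PHASES)),
         p_int = rep(0, n), time = 0),
    class = "crtsim_state"
  )
}
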