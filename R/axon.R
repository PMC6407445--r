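# Double-cable myelinated axon model (MRG-type).
#
# The fibre is a repeating 11-compartment internodal pattern
# (node, MYSA, FLUT, 6 x STIN, FLUT, MYSA) starting and ending on a node of
# Ranvier. Nodes carry fast Na+, persistent Na+ and slow K+ conductances
# plus a linear leak; paranodal and internodal compartments are passive,
# with the myelin sheath as a second (low-capacitance, low-conductance)
# membrane between the periaxonal space and the extracellular medium.
# Geometry and membrane constants for each supported fibre diameter are
# shipped in inst/extdata (transcribed from the published double-cable
# model this implementation follows).
#
# Internal units: mV, ms, uS, nF.

mrg_tables <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      geo <- read.delim(system.file("extdata", "mrg_fibre_geometry.tsv",
                                    package = "snsvta"))
      mem <- read.delim(system.file("extdata", "mrg_membrane_constants.tsv",
                                    package = "snsvta"))
      cache <<- list(geometry = geo,
                     membrane = setNames(mem$value, mem$parameter))
    }
    cache
  }
})

#' Build a double-cable axon morphology
#'
#' Constructs the compartmental morphology and passive/active electrical
#' parameters for a myelinated fibre of one of the tabulated diameters
#' (5.7 um is the diameter used throughout the SNS pipeline). The fibre has
#' `floor(length / internodal spacing) + 1` nodes of Ranvier (201 for a
#' 100 mm, 5.7 um fibre at 0.5 mm spacing). The resting state is computed
#' once at build time by relaxing the unstimulated fibre for 50 ms and is
#' cached in the returned object.
#'
#' @param fibre_diameter_um fibre diameter (um); must be one of the
#'   tabulated diameters.
#' @param total_length_mm fibre length (mm), > one internode (default 100).
#' @param temperature_C simulation temperature; gating rates are tabulated
#'   at 36 degC and Q10-scaled elsewhere (2.2 for Na activation, 2.9 for Na
#'   inactivation, 3.0 for slow K).
#' @return An object of class `sns_axon`: compartment table (`$comp`),
#'   electrical vectors ready for the integrator (`$geom`), node bookkeeping
#'   and the cached resting state (`$rest`).
#' @export
build_axon <- function(fibre_diameter_um = 5.7, total_length_mm = 100,
                       temperature_C = 36) {
  tabs <- mrg_tables()
  geo <- tabs$geometry
  row <- geo[abs(geo$fibre_diameter_um - fibre_diameter_um) < 1e-9, ]
  if (nrow(row) != 1) {
    stop("unsupported fibre diameter ", fibre_diameter_um,
         " um; supported: ", paste(geo$fibre_diameter_um, collapse = ", "),
         call. = FALSE)
  }
  if (!is.numeric(total_length_mm) || total_length_mm * 1000 < row$internode_um) {
    stop("total_length_mm must cover at least one internode (",
         row$internode_um / 1000, " mm)", call. = FALSE)
  }
  mem <- tabs$membrane

  n_inter <- floor(total_length_mm * 1000 / row$internode_um)
  n_nodes <- n_inter + 1
  stin_len <- (row$internode_um - row$node_length_um -
                 2 * row$mysa_length_um - 2 * row$flut_length_um) / row$stin_n

  seg_types <- c("node",
                 rep(c("MYSA", "FLUT", rep("STIN", row$stin_n), "FLUT",
                       "MYSA", "node"), n_inter))
  type_len <- c(node = row$node_length_um, MYSA = row$mysa_length_um,
                FLUT = row$flut_length_um, STIN = stin_len)
  type_diam <- c(node = row$node_diameter_um, MYSA = row$mysa_diameter_um,
                 FLUT = row$flut_diameter_um, STIN = row$stin_diameter_um)
  type_space <- c(node = row$space_node_um, MYSA = row$space_mysa_um,
                  FLUT = row$space_flut_um, STIN = row$space_stin_um)
  len <- type_len[seg_types]
  diam <- type_diam[seg_types]
  space <- type_space[seg_types]
  M <- length(seg_types)
  ends <- cumsum(len)
  centres_um <- ends - len / 2

  # axolemma: area uses the compartment's axon diameter
  area <- pi * diam * len                       # um^2
  cmem <- mem[["cm_axolemma"]] * area * 1e-5    # nF
  gpas <- numeric(M)
  gpas[seg_types == "MYSA"] <- mem[["g_mysa"]] * area[seg_types == "MYSA"] * 1e-2
  gpas[seg_types == "FLUT"] <- mem[["g_flut"]] * area[seg_types == "FLUT"] * 1e-2
  gpas[seg_types == "STIN"] <- mem[["g_stin"]] * area[seg_types == "STIN"] * 1e-2
  epas <- rep(mem[["e_pas"]], M)

  # myelin: area uses the full fibre diameter; 2*lamellae membranes in series
  nl2 <- 2 * row$lamellae
  area_my <- pi * fibre_diameter_um * len
  cmy <- (mem[["mycm"]] / nl2) * area_my * 1e-5
  gmy <- (mem[["mygm"]] / nl2) * area_my * 1e-2
  is_node <- seg_types == "node"
  cmy[is_node] <- 0
  gmy[is_node] <- 1e6  # no myelin at nodes: periaxonal tied to extracellular

  # axial conductances (series half-compartment resistances), uS
  rhoa_Mohm_um <- mem[["rhoa"]] * 1e-2   # 70 ohm cm = 0.7 Mohm um
  r_half_axial <- rhoa_Mohm_um * (len / 2) / (pi * diam^2 / 4)
  ga <- 1 / (r_half_axial[-M] + r_half_axial[-1])
  a_peri <- pi * ((diam / 2 + space)^2 - (diam / 2)^2)
  r_half_peri <- rhoa_Mohm_um * (len / 2) / a_peri
  gp <- 1 / (r_half_peri[-M] + r_half_peri[-1])

  area_node <- pi * row$node_diameter_um * row$node_length_um
  gbar <- c(gnaf = mem[["gnaf"]], gnap = mem[["gnap"]],
            gks = mem[["gks"]], gl = mem[["gl"]]) * area_node * 1e-2

  # nodal leak folded into the passive entries so the integrator adds the
  # voltage-gated part on top
  gpas[is_node] <- 0  # leak handled with the channels (gl within gbar)

  rate_scale <- c(2.2, 2.9, 3.0)^((temperature_C - 36) / 10)

  geom <- list(cmem = cmem, gpas = gpas, epas = epas, cmy = cmy, gmy = gmy,
               ga = ga, gp = gp,
               node_idx = as.integer(which(is_node) - 1L),
               gbar = as.numeric(gbar),
               ena = mem[["ena"]], ek = mem[["ek"]], el = mem[["el"]])

  morph <- structure(list(
    fibre_diameter_um = fibre_diameter_um,
    total_length_mm = M_total <- sum(len) / 1000,
    internode_um = row$internode_um,
    n_nodes = n_nodes,
    n_comp = M,
    comp = data.frame(type = seg_types, length_um = as.numeric(len),
                      diameter_um = as.numeric(diam),
                      centre_mm = centres_um / 1000),
    geom = geom,
    rate_scale = rate_scale,
    temperature_C = temperature_C
  ), class = "sns_axon")

  morph$rest <- settle_axon(morph)
  morph
}

# relax the unstimulated fibre to its resting state
settle_axon <- function(morph, duration_ms = 50, dt = 0.025) {
  M <- morph$n_comp
  vrest0 <- mrg_tables()$membrane[["vrest"]]
  gates0 <- matrix(rep(.gate_steady(vrest0, morph$rate_scale), morph$n_nodes),
                   nrow = morph$n_nodes, byrow = TRUE)
  zeros <- numeric(M)
  out <- .fiber_sim(morph$geom, ve_unit = zeros, onsets = numeric(0),
                    pw = 0, duration = duration_ms, dt = dt, amp = 0,
                    vi0 = rep(vrest0, M), vp0 = zeros, gates0 = gates0,
                    record_nodes = 0L, spike_thresh = -20, lockout = 1,
                    fast_forward = FALSE, rest_vi = rep(vrest0, M),
                    rest_vp = zeros, rest_gates = gates0,
                    early_abort = FALSE, return_vm = FALSE, vm_every = 10L,
                    rate_scale = morph$rate_scale, dt_quiet = dt)
  list(vi = out$vi, vp = out$vp, gates = out$gates)
}

#' @export
print.sns_axon <- function(x, ...) {
  cat(sprintf("sns_axon: %.3g um double-cable fibre, %.4g mm, %d nodes (%d compartments)\n",
              x$fibre_diameter_um, x$total_length_mm, x$n_nodes, x$n_comp))
  cat(sprintf("  internodal spacing %.3g mm; resting Vm %.2f mV at node 1\n",
              x$internode_um / 1000,
              x$rest$vi[x$geom$node_idx[1] + 1] -
                x$rest$vp[x$geom$node_idx[1] + 1]))
  invisible(x)
}

#' Simulate an axon driven by an extracellular pulse train
#'
#' Integrates the double-cable equations with backward Euler under the
#' extracellular drive `Ve(t) = unit_potentials * amplitude_scale * s(t)`,
#' where `s(t)` is the monophasic square pulse train of `train`. Spikes are
#' upward crossings of -20 mV at the recording node (10 nodes from the
#' distal end by default, away from the sealed ends) with a 1 ms lockout.
#'
#' @param morph an `sns_axon` from [build_axon()].
#' @param unit_potentials extracellular potential at each compartment centre
#'   for a unit (1 V) drive, in volts; length `morph$n_comp`.
#' @param train an `sns_stim` (frequency, pulse width, duration).
#' @param dt time step (ms); must be positive and at most 0.025.
#' @param amplitude_scale dimensionless multiplier of the unit-drive field.
#' @param record_nodes node indices (1-based) at which spikes are detected;
#'   the first is the primary recording node.
#' @param onsets_ms optional explicit pulse onset times overriding the
#'   train's regular grid (used e.g. for paired-pulse protocols).
#' @param fast_forward skip quiescent inter-pulse intervals by relaxing the
#'   gating variables analytically once every compartment is within 0.05 mV
#'   of rest (verified against full integration in the test suite).
#' @param dt_quiet coarser implicit step (ms) used in quiet spans, from
#'   15 ms after a pulse onset until just before the next pulse; backward
#'   Euler remains stable and the smallest passive time constant (~0.3 ms)
#'   stays well resolved. Set equal to `dt` for uniform stepping. At most
#'   0.025 ms.
#' @param early_abort stop as soon as one pulse window has failed the 1:1
#'   criterion (the outcome of [fires_one_to_one()] is then already FALSE).
#' @param return_vm also return a subsampled membrane-potential trace at the
#'   recording nodes.
#' @return Sorted numeric vector of spike times (ms) at the primary
#'   recording node, with attributes `all_spikes` (list per recording node),
#'   `aborted`, and optionally `vm`/`vm_times`.
#' @export
simulate_axon <- function(morph, unit_potentials, train, dt = 0.005,
                          amplitude_scale = 1,
                          record_nodes = NULL,
                          onsets_ms = NULL,
                          fast_forward = TRUE,
                          early_abort = FALSE,
                          return_vm = FALSE,
                          dt_quiet = 0.025) {
  stopifnot(inherits(morph, "sns_axon"))
  if (!is.numeric(dt) || dt <= 0 || dt > 0.025) {
    stop("dt must be in (0, 0.025] ms for a stable, accurate solve",
         call. = FALSE)
  }
  if (!is.numeric(dt_quiet) || dt_quiet <= 0 || dt_quiet > 0.025) {
    stop("dt_quiet must be in (0, 0.025] ms", call. = FALSE)
  }
  if (length(unit_potentials) != morph$n_comp) {
    stop("unit_potentials must have one value per compartment (",
         morph$n_comp, ")", call. = FALSE)
  }
  if (is.null(record_nodes)) record_nodes <- max(1L, morph$n_nodes - 10L)
  stopifnot(all(record_nodes >= 1), all(record_nodes <= morph$n_nodes))
  if (is.null(onsets_ms)) onsets_ms <- pulse_onsets(train)
  out <- .fiber_sim(morph$geom,
                    ve_unit = unit_potentials * 1000,  # V -> mV
                    onsets = as.numeric(onsets_ms),
                    pw = train$pulse_width_ms,
                    duration = train$duration_ms,
                    dt = dt, amp = amplitude_scale,
                    vi0 = morph$rest$vi, vp0 = morph$rest$vp,
                    gates0 = morph$rest$gates,
                    record_nodes = as.integer(record_nodes - 1L),
                    spike_thresh = -20, lockout = 1,
                    fast_forward = fast_forward,
                    rest_vi = morph$rest$vi, rest_vp = morph$rest$vp,
                    rest_gates = morph$rest$gates,
                    early_abort = early_abort,
                    return_vm = return_vm, vm_every = 10L,
                    rate_scale = morph$rate_scale,
                    dt_quiet = max(dt, dt_quiet))
  spikes <- sort(out$spikes[[1]])
  attr(spikes, "all_spikes") <- out$spikes
  attr(spikes, "aborted") <- out$aborted
  if (return_vm) {
    attr(spikes, "vm") <- out$vm
    attr(spikes, "vm_times") <- out$vm_times
  }
  spikes
}

#' 1:1 firing criterion
#'
#' TRUE iff every pulse onset is followed by exactly one spike before the
#' next onset (the last window extends to the train duration).
#'
#' @param spike_times numeric vector of spike times (ms).
#' @param train an `sns_stim`.
#' @param onsets_ms optional explicit onsets overriding the train's grid.
#' @return Logical scalar.
#' @export
fires_one_to_one <- function(spike_times, train, onsets_ms = NULL) {
  if (is.null(onsets_ms)) onsets_ms <- pulse_onsets(train)
  bounds <- c(onsets_ms[-1], train$duration_ms)
  for (q in seq_along(onsets_ms)) {
    n <- sum(spike_times >= onsets_ms[q] & spike_times < bounds[q])
    if (n != 1) return(FALSE)
  }
  length(onsets_ms) > 0
}

#' Activation threshold by bisection
#'
#' Finds the smallest amplitude scale at which the fibre fires 1:1 with the
#' pulse train, by doubling up to `max_scale` to bracket and then bisecting
#' until the bracket is narrower than `tol`. The returned value activates;
#' the returned value minus `tol` does not.
#'
#' @param morph an `sns_axon`.
#' @param unit_potentials per-compartment extracellular potential at unit
#'   drive (V).
#' @param train an `sns_stim`.
#' @param tol bracket width (amplitude-scale units).
#' @param max_scale largest amplitude scale tried; if the fibre does not
#'   activate there, `NA` is returned with attribute `no_activation = TRUE`
#'   (a distinct signal, not an error).
#' @param dt integrator time step (ms).
#' @return Threshold amplitude scale, or the tagged `NA` described above.
#' @export
find_threshold <- function(morph, unit_potentials, train, tol = 0.02,
                           max_scale = 64, dt = 0.005) {
  no_act <- structure(NA_real_, no_activation = TRUE)
  if (all(unit_potentials == 0)) return(no_act)
  activates <- function(scale) {
    sp <- simulate_axon(morph, unit_potentials, train, dt = dt,
                        amplitude_scale = scale, early_abort = TRUE)
    !attr(sp, "aborted") && fires_one_to_one(sp, train)
  }
  hi <- 1
  while (hi <= max_scale && !activates(hi)) hi <- hi * 2
  if (hi > max_scale) {
    if (!activates(max_scale)) return(no_act)
    hi <- max_scale
  }
  lo <- if (hi == 1) 0 else hi / 2
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (activates(mid)) hi <- mid else lo <- mid
  }
  hi
}
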