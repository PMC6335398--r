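#' @useDynLib abcdl, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data
#' @import tibble
NULL

GEN_TIME_YEARS <- 29

#' Convert calendar years to generations
#'
#' All internal times are in generations; configuration given in years is
#' converted with a human generation time of 29 years.
#'
#' @param years numeric vector of times in years (or kya * 1000).
#' @param generation_time years per generation (default 29).
#' @return times in generations.
#' @export
years_to_generations <- function(years, generation_time = GEN_TIME_YEARS) {
  years / generation_time
}

#' @rdname years_to_generations
#' @param generations numeric vector of times in generations.
#' @export
generations_to_years <- function(generations, generation_time = GEN_TIME_YEARS) {
  generations * generation_time
}

kya <- function(x) years_to_generations(x * 1000)

# Sampled populations, in the fixed axis order used for every joint SFS.
SAMPLED_POPS <- c("AFR", "EUR", "ASN", "AND", "IND", "PAP", "AUS", "NEAN", "DENI")
GHOST_POPS <- c("XE", "XN", "XD")

#' Sampled and ghost populations of the introgression models
#'
#' Nine sampled populations (seven modern human groups plus the Altai
#' Neanderthal and the Denisovan) and up to three unsampled "ghost"
#' populations: `XE`, an extinct hominin introgressing into Asian/Oceanian
#' ancestors; `XN`, a basal-Eurasian modern human group; and `XD`, a deeply
#' diverged hominin introgressing into Denisovans.
#'
#' @return a tibble with columns `code`, `sampled`, `description`.
#' @export
population_table <- function() {
  tibble::tibble(
    code = c(SAMPLED_POPS, GHOST_POPS),
    sampled = c(rep(TRUE, length(SAMPLED_POPS)), rep(FALSE, length(GHOST_POPS))),
    description = c(
      "African", "European", "East Asian", "Andamanese", "Indian",
      "Papuan", "Australian", "Altai Neanderthal", "Denisovan",
      "extinct archaic hominin (ghost)", "basal Eurasian modern human (ghost)",
      "deeply diverged hominin introgressing Denisova (ghost)"
    )
  )
}

prior_row <- function(name, family, a, b = NA_real_, units = "generations") {
  tibble::tibble(name = name, family = family, a = a, b = b, units = units)
}

uniform_prior <- function(name, lo, hi, units = "generations") {
  prior_row(name, "uniform", lo, hi, units)
}
log_uniform_prior <- function(name, lo, hi, units = "diploid Ne") {
  prior_row(name, "log_uniform", lo, hi, units)
}
fixed_prior <- function(name, value, units = "generations") {
  prior_row(name, "fixed", value, NA_real_, units)
}

# Default priors, in generations. Split-time windows are wide uniforms chosen
# to contain the published 95% credible intervals with margin; effective sizes
# are log-uniform on [1e2, 1e5]; archaic pulse fractions uniform on [0, 0.2];
# the mixture fraction at the origin of XE uniform on [0, 1]; continuous
# migration rates log-uniform on [1e-6, 1e-3] per generation.
default_time_priors <- function() {
  dplyr::bind_rows(
    uniform_prior("t_pap_aus",          kya(10),  kya(50)),
    uniform_prior("t_ea_an_i",          kya(15),  kya(55)),
    uniform_prior("t_asia_pacific",     kya(30),  kya(65)),
    uniform_prior("t_eur_asia_pacific", kya(40),  kya(90)),
    uniform_prior("t_eurasia_afr",      kya(60),  kya(220)),
    uniform_prior("t_nean_deni",        kya(200), kya(450)),
    uniform_prior("t_hominin",          kya(400), kya(800)),
    uniform_prior("t_hominin_er",       kya(800), kya(2400)),
    uniform_prior("t_deni_pac",         kya(15),  kya(55)),
    uniform_prior("t_xd_deni",          kya(30),  kya(150)),
    uniform_prior("t_nean_ooa",         kya(45),  kya(140))
  )
}

default_fraction_priors <- function() {
  dplyr::bind_rows(
    uniform_prior("f_deni_pac", 0, 0.2, "proportion"),
    uniform_prior("f_xd_deni",  0, 0.2, "proportion"),
    uniform_prior("f_nean_ooa", 0, 0.2, "proportion")
  )
}

default_size_priors <- function(demes) {
  dplyr::bind_rows(lapply(paste0("n_", tolower(demes)), function(nm) {
    log_uniform_prior(nm, 1e2, 1e5)
  }))
}

ANC_SIZES <- c("n_anc_pac", "n_anc_asia", "n_anc_asia_pacific", "n_anc_eurasia",
               "n_anc_amh", "n_anc_nd", "n_anc_hominin", "n_anc_root")

default_migration_priors <- function() {
  dplyr::bind_rows(lapply(c("m_afr_eur", "m_eur_asn", "m_pap_aus"), function(nm) {
    log_uniform_prior(nm, 1e-6, 1e-3, "migrants per lineage per generation")
  }))
}

event_row <- function(kind, time, source, dest, frac = NA_character_) {
  tibble::tibble(kind = kind, time_param = time, source = source,
                 dest = dest, fraction = frac)
}

constraint_row <- function(lo, hi) tibble::tibble(lo = lo, hi = hi)

# Backbone shared by all eight models: the modern-human topology, the
# Neanderthal pulse into the out-of-Africa ancestor, the Denisovan pulse into
# the Oceanian ancestor, the XD pulse into Denisovans, and the recent
# continuous migrations AFR<->EUR, EUR<->ASN, PAP<->AUS.
backbone_events <- function() {
  dplyr::bind_rows(
    event_row("split", "t_pap_aus", "PAP", "AUS"),
    event_row("split", "t_ea_an_i", "ASN", "AND"),
    event_row("split", "t_ea_an_i", "ASN", "IND"),
    event_row("pulse_admixture", "t_deni_pac", "DENI", "PAP", "f_deni_pac"),
    event_row("split", "t_asia_pacific", "ASN", "PAP"),
    event_row("split", "t_eur_asia_pacific", "ASN", "EUR"),
    event_row("pulse_admixture", "t_nean_ooa", "NEAN", "ASN", "f_nean_ooa"),
    event_row("split", "t_eurasia_afr", "AFR", "ASN"),
    event_row("pulse_admixture", "t_xd_deni", "XD", "DENI", "f_xd_deni"),
    event_row("split", "t_nean_deni", "DENI", "NEAN"),
    event_row("split", "t_hominin", "AFR", "DENI"),
    event_row("split", "t_hominin_er", "AFR", "XD"),
    event_row("continuous_migration", "t_eur_asia_pacific", "AFR", "EUR", "m_afr_eur"),
    event_row("continuous_migration", "t_eur_asia_pacific", "EUR", "ASN", "m_eur_asn"),
    event_row("continuous_migration", "t_pap_aus", "PAP", "AUS", "m_pap_aus")
  )
}

backbone_constraints <- function() {
  dplyr::bind_rows(
    constraint_row("t_pap_aus", "t_deni_pac"),
    constraint_row("t_deni_pac", "t_asia_pacific"),
    constraint_row("t_ea_an_i", "t_asia_pacific"),
    constraint_row("t_asia_pacific", "t_eur_asia_pacific"),
    constraint_row("t_eur_asia_pacific", "t_nean_ooa"),
    constraint_row("t_nean_ooa", "t_eurasia_afr"),
    constraint_row("t_eurasia_afr", "t_hominin"),
    constraint_row("t_nean_deni", "t_hominin"),
    constraint_row("t_hominin", "t_hominin_er"),
    constraint_row("t_xd_deni", "t_nean_deni")
  )
}

xe_pulse_events <- function() {
  event_row("pulse_admixture", "t_xe_asia", "XE", "ASN", "f_xe_asia")
}

xe_pulse_priors <- function() {
  dplyr::bind_rows(
    uniform_prior("t_xe_asia", kya(35), kya(80)),
    uniform_prior("f_xe_asia", 0, 0.2, "proportion")
  )
}

xe_pulse_constraints <- function(origin_param) {
  dplyr::bind_rows(
    constraint_row("t_asia_pacific", "t_xe_asia"),
    constraint_row("t_xe_asia", "t_eur_asia_pacific"),
    constraint_row("t_xe_asia", origin_param)
  )
}

#' Build one of the eight competing introgression models
#'
#' All models share a modern-human backbone (Out-of-Africa split, European
#' versus Asian/Pacific split, Asian and Oceanian sub-splits, recent continuous
#' migrations), a Neanderthal pulse into the Out-of-Africa ancestor, a
#' Denisovan pulse into the Oceanian ancestor and a pulse from a deeply
#' diverged hominin (XD) into Denisovans. They differ only in the additional
#' introgression scheme:
#'
#' * `A` — backbone only.
#' * `B` — a non-introgressed basal-Eurasian modern human ghost (XN) admixes
#'   into Europeans, diluting their Neanderthal ancestry.
#' * `C` — a second Neanderthal pulse into the Asian/Pacific ancestor.
#' * `D` — a second Denisovan pulse into the Asian/Pacific ancestor.
#' * `E`/`F`/`G`/`H` — an extinct archaic ghost (XE) pulses into the
#'   Asian/Pacific ancestor; XE is a Neanderthal sister (`E`), a Denisova
#'   sister (`F`), an outgroup of both (`G`), or a Neanderthal-Denisova
#'   admixture product (`H`). `E` and `F` are the `H` limits where the
#'   Denisovan share of XE is fixed at 0 and 1.
#'
#' @param label model letter, one of `"A"` to `"H"`.
#' @param config optional list. `config$priors` is a named list of prior
#'   overrides, each either `c(lo, hi)` (uniform) or a list with `family`
#'   (`"uniform"`, `"log_uniform"`, `"normal"`, `"fixed"`) and `a`, `b`.
#'   `config$archaic_sampling` is a named vector of sampling ages in
#'   generations for `NEAN` and `DENI` (default 0).
#' @return an object of class `demographic_model`.
#' @export
build_model <- function(label, config = list()) {
  label <- toupper(as.character(label)[1])
  if (!label %in% LETTERS[1:8]) {
    stop("unknown model label '", label, "' (expected one of A..H)")
  }
  demes <- c(SAMPLED_POPS, "XD")
  events <- backbone_events()
  constraints <- backbone_constraints()
  priors <- dplyr::bind_rows(default_time_priors(), default_fraction_priors(),
                             default_migration_priors())

  if (label == "B") {
    demes <- c(demes, "XN")
    events <- dplyr::bind_rows(
      events,
      event_row("pulse_admixture", "t_xn_eur", "XN", "EUR", "f_xn_eur"),
      event_row("split", "t_xn_split", "ASN", "XN")
    )
    priors <- dplyr::bind_rows(
      priors,
      uniform_prior("t_xn_split", kya(45), kya(200)),
      uniform_prior("t_xn_eur", kya(20), kya(70)),
      uniform_prior("f_xn_eur", 0, 0.5, "proportion")
    )
    constraints <- dplyr::bind_rows(
      constraints,
      constraint_row("t_xn_eur", "t_eur_asia_pacific"),
      constraint_row("t_eur_asia_pacific", "t_xn_split"),
      constraint_row("t_xn_split", "t_eurasia_afr")
    )
  } else if (label == "C") {
    events <- dplyr::bind_rows(
      events,
      event_row("pulse_admixture", "t_nean_asia", "NEAN", "ASN", "f_nean_asia")
    )
    priors <- dplyr::bind_rows(
      priors,
      uniform_prior("t_nean_asia", kya(30), kya(90)),
      uniform_prior("f_nean_asia", 0, 0.2, "proportion")
    )
    constraints <- dplyr::bind_rows(
      constraints,
      constraint_row("t_asia_pacific", "t_nean_asia"),
      constraint_row("t_nean_asia", "t_eur_asia_pacific")
    )
  } else if (label == "D") {
    events <- dplyr::bind_rows(
      events,
      event_row("pulse_admixture", "t_deni_asia", "DENI", "ASN", "f_deni_asia")
    )
    priors <- dplyr::bind_rows(
      priors,
      uniform_prior("t_deni_asia", kya(30), kya(90)),
      uniform_prior("f_deni_asia", 0, 0.2, "proportion")
    )
    constraints <- dplyr::bind_rows(
      constraints,
      constraint_row("t_asia_pacific", "t_deni_asia"),
      constraint_row("t_deni_asia", "t_eur_asia_pacific")
    )
  } else if (label %in% c("E", "F", "G", "H")) {
    demes <- c(demes, "XE")
    events <- dplyr::bind_rows(events, xe_pulse_events())
    priors <- dplyr::bind_rows(priors, xe_pulse_priors())
    if (label == "E") {
      events <- dplyr::bind_rows(
        events,
        event_row("admixed_origin", "t_xe_nean_split", "NEAN;DENI", "XE", "0")
      )
      priors <- dplyr::bind_rows(priors, uniform_prior("t_xe_nean_split", kya(150), kya(430)))
      constraints <- dplyr::bind_rows(
        constraints, xe_pulse_constraints("t_xe_nean_split"),
        constraint_row("t_xe_nean_split", "t_nean_deni")
      )
    } else if (label == "F") {
      events <- dplyr::bind_rows(
        events,
        event_row("admixed_origin", "t_xe_deni_split", "NEAN;DENI", "XE", "1")
      )
      priors <- dplyr::bind_rows(priors, uniform_prior("t_xe_deni_split", kya(150), kya(430)))
      constraints <- dplyr::bind_rows(
        constraints, xe_pulse_constraints("t_xe_deni_split"),
        constraint_row("t_xe_deni_split", "t_nean_deni")
      )
    } else if (label == "G") {
      events <- dplyr::bind_rows(
        events,
        event_row("split", "t_xe_nd_split", "DENI", "XE")
      )
      priors <- dplyr::bind_rows(priors, uniform_prior("t_xe_nd_split", kya(210), kya(700)))
      constraints <- dplyr::bind_rows(
        constraints, xe_pulse_constraints("t_xe_nd_split"),
        constraint_row("t_nean_deni", "t_xe_nd_split"),
        constraint_row("t_xe_nd_split", "t_hominin")
      )
    } else {
      events <- dplyr::bind_rows(
        events,
        event_row("admixed_origin", "t_xe_origin", "NEAN;DENI", "XE", "f_xe_deni")
      )
      priors <- dplyr::bind_rows(
        priors,
        uniform_prior("t_xe_origin", kya(150), kya(440)),
        uniform_prior("f_xe_deni", 0, 1, "proportion")
      )
      constraints <- dplyr::bind_rows(
        constraints, xe_pulse_constraints("t_xe_origin"),
        constraint_row("t_xe_origin", "t_nean_deni")
      )
    }
  }

  priors <- dplyr::bind_rows(priors, default_size_priors(demes),
                             dplyr::bind_rows(lapply(ANC_SIZES, function(nm) {
                               log_uniform_prior(nm, 1e2, 1e5)
                             })))

  archaic_sampling <- c(NEAN = 0, DENI = 0)
  if (!is.null(config$archaic_sampling)) {
    bad <- setdiff(names(config$archaic_sampling), c("NEAN", "DENI"))
    if (length(bad)) stop("archaic_sampling for unknown population(s): ", paste(bad, collapse = ", "))
    archaic_sampling[names(config$archaic_sampling)] <- config$archaic_sampling
  }

  model <- structure(
    list(label = label, demes = demes, sampled = SAMPLED_POPS,
         events = events, priors = priors, constraints = constraints,
         archaic_sampling = archaic_sampling),
    class = "demographic_model"
  )
  if (!is.null(config$priors)) model <- override_priors(model, config$priors)
  validate_model(model)
  model
}

override_priors <- function(model, overrides) {
  for (nm in names(overrides)) {
    i <- which(model$priors$name == nm)
    if (length(i) != 1) {
      stop("prior override references parameter '", nm,
           "' absent from model ", model$label)
    }
    ov <- overrides[[nm]]
    if (is.numeric(ov) && length(ov) == 2) {
      model$priors$family[i] <- "uniform"
      model$priors$a[i] <- ov[1]; model$priors$b[i] <- ov[2]
    } else if (is.numeric(ov) && length(ov) == 1) {
      model$priors$family[i] <- "fixed"
      model$priors$a[i] <- ov; model$priors$b[i] <- NA_real_
    } else if (is.list(ov)) {
      model$priors$family[i] <- ov$family
      model$priors$a[i] <- ov$a
      model$priors$b[i] <- if (is.null(ov$b)) NA_real_ else ov$b
    } else stop("unrecognized prior override for '", nm, "'")
  }
  model
}

validate_model <- function(model) {
  ev <- model$events
  referenced <- unique(c(ev$time_param,
                         ev$fraction[is.na(suppressWarnings(as.numeric(ev$fraction)))]))
  referenced <- referenced[!is.na(referenced)]
  missing <- setdiff(referenced, model$priors$name)
  if (length(missing)) {
    stop("parameters without a prior: ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(model$priors$name)) stop("duplicated prior names")
  with(model$priors, {
    bad <- family %in% c("uniform", "log_uniform") & !(a <= b)
    if (any(bad)) stop("prior with lower > upper: ", paste(name[bad], collapse = ", "))
  })
  cn <- unique(c(model$constraints$lo, model$constraints$hi))
  missing <- setdiff(cn, model$priors$name)
  if (length(missing)) stop("constraint references unknown parameter: ",
                            paste(missing, collapse = ", "))
  invisible(model)
}

#' @export
print.demographic_model <- function(x, ...) {
  cat("Demographic model", x$label, "-", length(x$demes), "demes,",
      nrow(x$events), "events,", nrow(x$priors), "parameters\n")
  cat("Sampled populations:", paste(x$sampled, collapse = " "), "\n")
  print(x$events, n = nrow(x$events))
  invisible(x)
}

#' Draw parameter vectors from a model's joint prior
#'
#' Draws each parameter from its marginal prior and enforces the model's
#' ordering constraints (e.g. the Neanderthal-Denisova split predating the
#' hominin root) by rejection resampling, so accepted vectors follow the joint
#' prior truncated to the constraint region.
#'
#' @param model a `demographic_model`.
#' @param n number of draws.
#' @param max_tries maximum resampling rounds before giving up.
#' @return a tibble with one row per draw and one column per parameter.
#' @export
sample_parameters <- function(model, n = 1, max_tries = 1000) {
  pr <- model$priors
  draw <- function(m) {
    out <- matrix(NA_real_, nrow = m, ncol = nrow(pr),
                  dimnames = list(NULL, pr$name))
    for (i in seq_len(nrow(pr))) {
      out[, i] <- switch(pr$family[i],
        uniform = stats::runif(m, pr$a[i], pr$b[i]),
        log_uniform = exp(stats::runif(m, log(pr$a[i]), log(pr$b[i]))),
        normal = stats::rnorm(m, pr$a[i], pr$b[i]),
        fixed = rep(pr$a[i], m),
        stop("unknown prior family: ", pr$family[i])
      )
    }
    out
  }
  ok_rows <- function(x) {
    ok <- rep(TRUE, nrow(x))
    for (j in seq_len(nrow(model$constraints))) {
      ok <- ok & (x[, model$constraints$lo[j]] < x[, model$constraints$hi[j]])
    }
    ok
  }
  acc <- matrix(NA_real_, 0, nrow(pr), dimnames = list(NULL, pr$name))
  tries <- 0
  while (nrow(acc) < n) {
    tries <- tries + 1
    if (tries > max_tries) {
      stop("constraints unsatisfiable: no accepted draw in ", max_tries, " rounds")
    }
    x <- draw(max(n * 2, 16))
    x <- x[ok_rows(x), , drop = FALSE]
    if (nrow(x)) acc <- rbind(acc, x)
  }
  out <- tibble::as_tibble(acc[seq_len(n), , drop = FALSE])
  class(out) <- c("parameter_draws", class(out))
  out
}

#' Check that a parameter vector satisfies a model's constraints
#' @param model a `demographic_model`.
#' @param params a single-row tibble or named numeric vector.
#' @return `TRUE`/`FALSE`.
#' @export
satisfies_constraints <- function(model, params) {
  p <- as_param_vec(params)
  all(vapply(seq_len(nrow(model$constraints)), function(j) {
    p[[model$constraints$lo[j]]] < p[[model$constraints$hi[j]]]
  }, logical(1)))
}

as_param_vec <- function(params) {
  if (is.data.frame(params)) {
    stopifnot(nrow(params) == 1)
    params <- unlist(params[1, , drop = TRUE])
  }
  params
}

frac_value <- function(frac, p) {
  num <- suppressWarnings(as.numeric(frac))
  if (!is.na(num)) num else unname(p[[frac]])
}

#' Translate a model plus a parameter vector into simulator input
#'
#' Produces the simulator-neutral description consumed by the coalescent
#' engine: initial deme sizes, the backward migration-rate matrix, and a
#' time-ordered table of instantaneous events (mass lineage movements, size
#' changes, migration-rate changes), all in generations. Pulses with fraction
#' zero are pruned, as is the second branch of an admixed origin whose first
#' fraction is one, so structurally equivalent models yield identical tables.
#'
#' @param model a `demographic_model`.
#' @param params one draw, as returned by [sample_parameters()].
#' @return list with `demes`, `sampled`, `sizes0`, `mig0`, `events` (tibble
#'   with columns `time`, `type`, `a`, `b`, `p`), `sampling_times`.
#' @export
to_simulator_spec <- function(model, params) {
  p <- as_param_vec(params)
  demes <- model$demes
  sizes0 <- stats::setNames(
    vapply(paste0("n_", tolower(demes)), function(nm) unname(p[[nm]]), numeric(1)),
    demes
  )
  mig0 <- matrix(0, length(demes), length(demes), dimnames = list(demes, demes))

  rows <- list()
  add <- function(time, type, a, b = NA_character_, val = NA_real_) {
    rows[[length(rows) + 1]] <<- tibble::tibble(time = time, type = type,
                                                a = a, b = b, p = val)
  }

  # ancestral-size parameter attached to each backbone split carrier
  anc_size <- c(t_pap_aus = "n_anc_pac", t_ea_an_i = "n_anc_asia",
                t_asia_pacific = "n_anc_asia_pacific",
                t_eur_asia_pacific = "n_anc_eurasia",
                t_eurasia_afr = "n_anc_amh", t_nean_deni = "n_anc_nd",
                t_hominin = "n_anc_hominin", t_hominin_er = "n_anc_root")

  ev <- model$events
  for (i in seq_len(nrow(ev))) {
    kind <- ev$kind[i]
    tpar <- ev$time_param[i]
    tt <- unname(p[[tpar]])
    if (kind == "split") {
      # backward join: lineages of the derived deme (dest) move into source
      add(tt, "mass_move", ev$dest[i], ev$source[i], 1)
      if (tpar %in% names(anc_size)) {
        add(tt, "set_size", ev$source[i], val = unname(p[[anc_size[[tpar]]]]))
      }
    } else if (kind == "pulse_admixture") {
      f <- frac_value(ev$fraction[i], p)
      if (f < 0 || f > 1) stop("pulse fraction outside [0,1]: ", ev$fraction[i])
      if (f > 0) add(tt, "mass_move", ev$dest[i], ev$source[i], f)
    } else if (kind == "admixed_origin") {
      src <- strsplit(ev$source[i], ";", fixed = TRUE)[[1]]
      stopifnot(length(src) == 2)
      f <- frac_value(ev$fraction[i], p)  # share of the second source
      if (f > 0) add(tt, "mass_move", ev$dest[i], src[2], f)
      if (f < 1) add(tt, "mass_move", ev$dest[i], src[1], 1)
    } else if (kind == "continuous_migration") {
      r <- frac_value(ev$fraction[i], p)
      mig0[ev$source[i], ev$dest[i]] <- r
      mig0[ev$dest[i], ev$source[i]] <- r
      # switched off once either partner merges away
      add(tt, "set_mig", ev$source[i], ev$dest[i], 0)
      add(tt, "set_mig", ev$dest[i], ev$source[i], 0)
    } else stop("unknown event kind: ", kind)
  }
  events <- dplyr::bind_rows(rows)
  events <- events[order(events$time), , drop = FALSE]  # stable sort keeps tie order

  if (any(events$time <= 0)) stop("event times must be strictly positive")
  sampling_times <- stats::setNames(rep(0, length(demes)), demes)
  sampling_times[names(model$archaic_sampling)] <- model$archaic_sampling
  moved <- events$type == "mass_move"
  for (d in names(model$archaic_sampling)) {
    st <- model$archaic_sampling[[d]]
    if (st > 0) {
      clash <- moved & (events$a == d | events$b == d) & events$time < st
      if (any(clash)) {
        stop("event at time ", min(events$time[clash]),
             " predates the sampling age of ", d)
      }
    }
  }

  structure(list(demes = demes, sampled = model$sampled, sizes0 = sizes0,
                 mig0 = mig0, events = events, sampling_times = sampling_times),
            class = "simulator_spec")
}

#' Serialize / restore a demographic model as YAML
#'
#' The round trip `model_from_yaml(model_to_yaml(m))` is the identity.
#'
#' @param model a `demographic_model`.
#' @param path file path; for `model_to_yaml`, where to write.
#' @return `model_to_yaml` returns `path` invisibly; `model_from_yaml` a model.
#' @export
model_to_yaml <- function(model, path) {
  doc <- list(
    label = model$label,
    demes = as.list(model$demes),
    archaic_sampling = as.list(model$archaic_sampling),
    events = lapply(seq_len(nrow(model$events)), function(i) {
      as.list(model$events[i, ])
    }),
    priors = lapply(seq_len(nrow(model$priors)), function(i) {
      as.list(model$priors[i, ])
    }),
    constraints = lapply(seq_len(nrow(model$constraints)), function(i) {
      as.list(model$constraints[i, ])
    })
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname model_to_yaml
#' @export
model_from_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  fix_na <- function(x) lapply(x, function(row) {
    lapply(row, function(v) if (is.null(v)) NA else v)
  })
  model <- structure(
    list(label = doc$label,
         demes = unlist(doc$demes),
         sampled = SAMPLED_POPS,
         events = dplyr::bind_rows(lapply(fix_na(doc$events), tibble::as_tibble)),
         priors = dplyr::bind_rows(lapply(fix_na(doc$priors), tibble::as_tibble)),
         constraints = dplyr::bind_rows(lapply(doc$constraints, tibble::as_tibble)),
         archaic_sampling = unlist(doc$archaic_sampling)),
    class = "demographic_model"
  )
  validate_model(model)
  model
}

#' Built-in point-estimate parameter sets
#'
#' Published posterior-mean calibrations for the two best-supported models
#' (the Denisova-sister ghost model `F` and the admixed-ghost model `H`), in
#' generations, completed with the package's default effective sizes and
#' migration rates (the size calibration follows literature-standard values
#' for human and archaic demography). For other labels the shared backbone
#' values from `H` are used and model-specific parameters sit at their prior
#' midpoints.
#'
#' @param label model letter.
#' @return a single-row tibble of parameters for [build_model()] of `label`.
#' @export
published_point_estimates <- function(label = "H") {
  label <- toupper(label)
  base <- c(
    t_pap_aus = kya(31.88), t_ea_an_i = kya(39.54), t_asia_pacific = kya(46.95),
    t_eur_asia_pacific = kya(57.85), t_eurasia_afr = kya(121.38),
    t_nean_deni = kya(314.07), t_hominin = kya(558.22),
    t_hominin_er = kya(1492.86),
    t_deni_pac = kya(43.10), f_deni_pac = 0.016,
    t_xd_deni = kya(77.90), f_xd_deni = 0.013,
    t_xe_asia = kya(51.03), f_xe_asia = 0.026,
    t_nean_ooa = kya(69.47), f_nean_ooa = 0.013,
    t_xe_origin = kya(304.41), f_xe_deni = 0.511
  )
  if (label == "F") {
    base[c("t_pap_aus", "t_ea_an_i", "t_asia_pacific", "t_eur_asia_pacific",
           "t_eurasia_afr", "t_nean_deni", "t_hominin", "t_hominin_er",
           "t_deni_pac", "f_deni_pac", "t_xd_deni", "f_xd_deni",
           "t_xe_asia", "f_xe_asia", "t_nean_ooa", "f_nean_ooa")] <-
      c(kya(31.37), kya(37.77), kya(47.60), kya(56.60), kya(137.68),
        kya(320.25), kya(531.23), kya(1474.61),
        kya(43.12), 0.016, kya(68.02), 0.011,
        kya(53.73), 0.034, kya(77.49), 0.019)
    base <- base[setdiff(names(base), c("t_xe_origin", "f_xe_deni"))]
    base <- c(base, t_xe_deni_split = kya(279.16))
  }
  sizes <- c(
    n_afr = 24000, n_eur = 10000, n_asn = 10000, n_and = 5000, n_ind = 10000,
    n_pap = 5000, n_aus = 5000, n_nean = 2500, n_deni = 2500,
    n_xd = 10000, n_xe = 2500, n_xn = 10000,
    n_anc_pac = 5000, n_anc_asia = 10000, n_anc_asia_pacific = 10000,
    n_anc_eurasia = 5000, n_anc_amh = 15000, n_anc_nd = 5000,
    n_anc_hominin = 15000, n_anc_root = 15000
  )
  mig <- c(m_afr_eur = 5e-5, m_eur_asn = 5e-5, m_pap_aus = 5e-5)
  # models without published estimates get nominal values consistent with the
  # backbone ordering: mid-window pulse times and 2% archaic pulses
  extras <- c(
    t_xn_split = mean(c(base[["t_eur_asia_pacific"]], base[["t_eurasia_afr"]])),
    t_xn_eur = kya(40), f_xn_eur = 0.1,
    t_nean_asia = mean(c(base[["t_asia_pacific"]], base[["t_eur_asia_pacific"]])),
    f_nean_asia = 0.02,
    t_deni_asia = mean(c(base[["t_asia_pacific"]], base[["t_eur_asia_pacific"]])),
    f_deni_asia = 0.02,
    t_xe_nean_split = kya(304.41),
    t_xe_nd_split = mean(c(base[["t_nean_deni"]], base[["t_hominin"]]))
  )
  vals <- c(base, sizes, mig, extras[setdiff(names(extras), names(base))])

  model <- build_model(label)
  need <- model$priors$name
  missing <- setdiff(need, names(vals))
  if (length(missing)) {
    stop("no point estimate available for: ", paste(missing, collapse = ", "))
  }
  out <- tibble::as_tibble(as.list(vals[need]))
  class(out) <- c("parameter_draws", class(out))
  stopifnot(satisfies_constraints(model, out))
  out
}
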