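#' Observer detection/placement model
#'
#' The latent process a simulated observer follows: per-item-class
#' detection probabilities, a seasonal multiplier on herbaceous-species
#' detectability (herbs dormant in late autumn are invisible to a visitor),
#' a false-positive rate per absent item, and an edge-bias scale for plot
#' placement (placement density proportional to `exp(-d / lambda)` with
#' `d` the distance to the patch edge; `lambda = Inf` means uniform
#' placement).
#'
#' Defaults encode the contrast between trained experts (high, uniform
#' detection; core-area placement) and non-experts (woody species detected
#' almost as well as experts, herbaceous species much less, structures and
#' pressures in between; occasional false positives; plots drawn towards
#' the edge near roads and paths).
#'
#' @param status `"expert"` or `"non_expert"`.
#' @param detect_prob named numeric vector with elements `woody`,
#'   `herbaceous`, `structure`, `pressure`, all in \[0, 1\].
#' @param season_factor multiplier in \[0, 1\] on herbaceous detectability
#'   (1 = peak season, small values = late-autumn visit).
#' @param false_positive_rate probability of recording an absent item.
#' @param edge_scale_lambda placement bias scale in meters (> 0, possibly
#'   `Inf`).
#' @return an object of class `observer_model`.
#' @export
observer_model <- function(status,
                           detect_prob = NULL,
                           season_factor = 1,
                           false_positive_rate = NULL,
                           edge_scale_lambda = NULL) {
  status <- match_level(status, OBSERVER_LEVELS, "observer_status")
  if (is.null(detect_prob)) {
    detect_prob <- if (status == "expert") {
      c(woody = 0.9, herbaceous = 0.9, structure = 0.9, pressure = 0.9)
    } else {
      c(woody = 0.85, herbaceous = 0.35, structure = 0.6, pressure = 0.5)
    }
  }
  need <- c("woody", "herbaceous", "structure", "pressure")
  miss <- setdiff(need, names(detect_prob))
  if (length(miss) > 0) {
    stop("detect_prob missing element(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(detect_prob < 0 | detect_prob > 1) ||
      season_factor < 0 || season_factor > 1) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(false_positive_rate)) {
    false_positive_rate <- if (status == "expert") 0 else 0.01
  }
  if (false_positive_rate < 0 || false_positive_rate > 1) {
    stop("false_positive_rate must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(edge_scale_lambda)) {
    edge_scale_lambda <- if (status == "expert") Inf else 5
  }
  if (edge_scale_lambda <= 0) {
    stop("edge_scale_lambda must be > 0", call. = FALSE)
  }
  structure(
    list(status = status, detect_prob = detect_prob[need],
         season_factor = season_factor,
         false_positive_rate = false_positive_rate,
         edge_scale_lambda = edge_scale_lambda),
    class = "observer_model"
  )
}

#' Generate a synthetic habitat protocol
#'
#' Builds an assessment template of the requested size: a checklist of
#' structure/function items (alternating natural features and
#' degradation-absence indicators), a typical-species list with integer
#' weights drawn uniformly from \{1, 2, 3\} and a woody/herbaceous split,
#' and a pressure catalogue. Deterministic given the seed.
#'
#' @param n_structures number of checklist items (>= 1).
#' @param n_species number of typical species (>= 1).
#' @param n_pressures number of catalogue activities (>= 1).
#' @param prop_woody proportion of typical species that are woody
#'   (default 0.5; the count is rounded).
#' @param habitat_code habitat code for the generated protocol.
#' @param seed integer RNG seed.
#' @return a [habitat_protocol()].
#' @export
generate_protocol <- function(n_structures = 10, n_species = 8,
                              n_pressures = 6, prop_woody = 0.5,
                              habitat_code = "9560", seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  stopifnot(n_structures >= 1, n_species >= 1, n_pressures >= 1,
            prop_woody >= 0, prop_woody <= 1)
  set.seed(as.integer(seed))
  sf <- data.frame(
    item_id = sprintf("sf%02d", seq_len(n_structures)),
    label = sprintf("structure/function indicator %d", seq_len(n_structures)),
    item_class = rep_len(c("natural_feature", "degradation_absence"),
                         n_structures))
  n_woody <- round(prop_woody * n_species)
  ts <- data.frame(
    species_id = sprintf("sp%02d", seq_len(n_species)),
    weight = sample(1:3, n_species, replace = TRUE),
    growth_form = sample(rep(c("woody", "herbaceous"),
                             c(n_woody, n_species - n_woody))))
  pc <- data.frame(
    activity_code = sprintf("act%02d", seq_len(n_pressures)),
    label = sprintf("activity %d", seq_len(n_pressures)))
  habitat_protocol(habitat_code, sf, ts, pc)
}

#' Sample plot locations inside a habitat patch, with optional edge bias
#'
#' Rejection sampling: locations are proposed uniformly in the patch and
#' accepted with probability `exp(-d / lambda)` where `d` is the distance
#' to the patch edge — small `lambda` concentrates plots near the edge,
#' `lambda = Inf` gives uniform placement. All returned points are strictly
#' inside the patch. Deterministic given the seed.
#'
#' @param polygon a [habitat_polygon()].
#' @param n number of locations (>= 1).
#' @param lambda edge-bias scale in meters (> 0 or `Inf`).
#' @param seed integer RNG seed.
#' @param max_proposals proposal budget before giving up (default 1e6).
#' @return an `n` x 2 matrix of coordinates.
#' @export
sample_plot_locations <- function(polygon, n, lambda = Inf, seed,
                                  max_proposals = 1e6) {
  stopifnot(inherits(polygon, "habitat_polygon"), n >= 1, lambda > 0)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  set.seed(as.integer(seed))
  all_x <- unlist(lapply(polygon$parts, function(p) p$exterior[, 1]))
  all_y <- unlist(lapply(polygon$parts, function(p) p$exterior[, 2]))
  out <- matrix(NA_real_, n, 2)
  got <- 0L
  tries <- 0L
  while (got < n) {
    tries <- tries + 1L
    if (tries > max_proposals) {
      stop("rejection sampling stalled after ", max_proposals,
           " proposals; consider a larger lambda", call. = FALSE)
    }
    pt <- c(stats::runif(1, min(all_x), max(all_x)),
            stats::runif(1, min(all_y), max(all_y)))
    if (!point_in_polygon(pt, polygon)) next
    d <- distance_to_edge(pt, polygon)
    if (d <= 0) next  # strictly inside
    acc <- if (is.infinite(lambda)) 1 else exp(-d / lambda)
    if (stats::runif(1) <= acc) {
      got <- got + 1L
      out[got, ] <- pt
    }
  }
  out
}

#' Generate the latent truth of one plot
#'
#' Encodes the marginal-conditions gradient: conditions degrade towards
#' the patch edge. Each checklist item and each typical species is truly
#' present independently with probability `plogis(alpha + beta * d)`
#' (`d` = distance to edge, meters), so interior plots are in better
#' condition. The number of pressures acting on the plot is Poisson with
#' mean `pressure_rate_edge * exp(-d / pressure_decay)` (truncated at the
#' catalogue size), and intensities are more often high near the edge.
#'
#' @param location numeric `c(x, y)` inside the patch.
#' @param protocol a [habitat_protocol()].
#' @param polygon the patch [habitat_polygon()].
#' @param gradient list with `alpha`, `beta` (logistic presence gradient),
#'   `pressure_rate_edge` (mean pressure count at the edge) and
#'   `pressure_decay` (meters). Defaults: `alpha = 0`, `beta = 0.15`,
#'   `pressure_rate_edge = 2`, `pressure_decay = 20`.
#' @param seed integer RNG seed.
#' @return an object of class `plot_truth`: list with `location`,
#'   `d_edge`, `items_true` (checklist ids), `species_true`
#'   (a [species_observations()] frame of truly present species) and
#'   `pressures_true` (a [pressure_records()] frame).
#' @export
generate_truth <- function(location, protocol, polygon,
                           gradient = list(), seed) {
  stopifnot(inherits(protocol, "habitat_protocol"),
            inherits(polygon, "habitat_polygon"))
  if (missing(seed)) stop("seed is required", call. = FALSE)
  g <- utils::modifyList(
    list(alpha = 0, beta = 0.15, pressure_rate_edge = 2,
         pressure_decay = 20),
    gradient)
  d <- distance_to_edge(location, polygon)
  set.seed(as.integer(seed))
  p_good <- stats::plogis(g$alpha + g$beta * d)

  sf_ids <- protocol$sf_checklist$item_id
  items_true <- sf_ids[stats::runif(length(sf_ids)) < p_good]

  sp <- protocol$typical_species
  present <- stats::runif(nrow(sp)) < p_good
  # condition classes of present species: better interior plots carry more
  # abundant, more vital populations
  w_edge <- if (is.infinite(g$pressure_decay)) 0 else exp(-d / g$pressure_decay)
  ab_probs <- (1 - w_edge) * c(0.05, 0.15, 0.35, 0.45) +
    w_edge * c(0.3, 0.3, 0.25, 0.15)
  vi_probs <- (1 - w_edge) * c(0.05, 0.25, 0.7) + w_edge * c(0.3, 0.4, 0.3)
  n_pres <- sum(present)
  species_true <- species_observations(
    sp$species_id[present],
    sample(ABUNDANCE_LEVELS, n_pres, replace = TRUE, prob = ab_probs),
    sample(VITALITY_LEVELS, n_pres, replace = TRUE, prob = vi_probs))

  pc <- protocol$pressure_catalogue$activity_code
  n_press <- min(stats::rpois(1, g$pressure_rate_edge * w_edge), length(pc))
  int_probs <- (1 - w_edge) * c(0.7, 0.25, 0.05) + w_edge * c(0.3, 0.4, 0.3)
  pressures_true <- pressure_records(
    sample(pc, n_press),
    sample(INTENSITY_LEVELS, n_press, replace = TRUE, prob = int_probs),
    sample(ROLE_LEVELS, n_press, replace = TRUE, prob = c(0.3, 0.2, 0.5)))

  structure(
    list(location = as.numeric(location), d_edge = d,
         items_true = items_true, species_true = species_true,
         pressures_true = pressures_true),
    class = "plot_truth"
  )
}

#' Simulate what one observer records on a plot
#'
#' Detection thinning of the latent truth: every truly present item is
#' recorded with the observer's detection probability for its class
#' (herbaceous species additionally multiplied by the season factor), and
#' every absent protocol item is recorded with the observer's
#' false-positive rate. Abundance and vitality of detected species are
#' copied from the truth; false-positive species are recorded in the
#' lowest classes (abundance `rare`, vitality `poor`) — spurious records
#' mimic the faint singleton sightings seen in real non-expert data.
#'
#' @param truth a [generate_truth()] result.
#' @param observer an [observer_model()].
#' @param protocol the plot's [habitat_protocol()].
#' @param plot_id,observer_id identifiers for the produced record.
#' @param habitat_code habitat code of the record (defaults to the
#'   protocol's).
#' @param seed integer RNG seed.
#' @return a [plot_record()].
#' @export
simulate_observation <- function(truth, observer, protocol, plot_id,
                                 observer_id,
                                 habitat_code = protocol$habitat_code,
                                 seed) {
  stopifnot(inherits(truth, "plot_truth"),
            inherits(observer, "observer_model"),
            inherits(protocol, "habitat_protocol"))
  if (missing(seed)) stop("seed is required", call. = FALSE)
  set.seed(as.integer(seed))
  dp <- observer$detect_prob
  fpr <- observer$false_positive_rate

  sf_ids <- protocol$sf_checklist$item_id
  is_true <- sf_ids %in% truth$items_true
  p_rec <- ifelse(is_true, dp["structure"], fpr)
  structures <- sf_ids[stats::runif(length(sf_ids)) < p_rec]

  sp <- protocol$typical_species
  p_detect <- ifelse(sp$growth_form == "herbaceous",
                     dp["herbaceous"] * observer$season_factor, dp["woody"])
  truly <- match(sp$species_id, truth$species_true$species_id)
  p_rec <- ifelse(!is.na(truly), p_detect, fpr)
  seen <- stats::runif(nrow(sp)) < p_rec
  idx <- which(seen)
  species_obs <- species_observations(
    sp$species_id[idx],
    ifelse(is.na(truly[idx]), "rare",
           truth$species_true$abundance[truly[idx]]),
    ifelse(is.na(truly[idx]), "poor",
           truth$species_true$vitality[truly[idx]]))

  pc <- protocol$pressure_catalogue$activity_code
  truly_p <- match(pc, truth$pressures_true$activity_code)
  p_rec <- ifelse(!is.na(truly_p), dp["pressure"], fpr)
  seen_p <- stats::runif(length(pc)) < p_rec
  idx <- which(seen_p)
  pressures <- pressure_records(
    pc[idx],
    ifelse(is.na(truly_p[idx]), "low",
           truth$pressures_true$intensity[truly_p[idx]]),
    ifelse(is.na(truly_p[idx]), "both",
           truth$pressures_true$role[truly_p[idx]]))

  plot_record(plot_id, habitat_code, observer_id, observer$status,
              truth$location[1], truth$location[2],
              structures_present = structures,
              species_obs = species_obs, pressures = pressures)
}

#' Simulation configuration
#'
#' Bundles everything [simulate_survey()] needs. Defaults describe one
#' habitat type surveyed the way national assessments pair expert and
#' citizen-science effort: a 100 m x 100 m patch, 6 expert plots shared by
#' 2 experts (each expert records several plots) and 30 non-expert plots
#' recorded by 30 distinct non-expert observers (one plot each).
#'
#' @param site_code,habitat_code identifiers of the simulated survey.
#' @param polygon patch [habitat_polygon()] (default 100 m square).
#' @param protocol a [habitat_protocol()], or `NULL` to generate one from
#'   `protocol_spec`.
#' @param protocol_spec list of arguments for [generate_protocol()]
#'   (sizes, `prop_woody`).
#' @param n_expert_plots,n_nonexpert_plots plot counts per group.
#' @param n_experts number of distinct expert observer ids.
#' @param expert,non_expert [observer_model()]s for the two groups.
#' @param gradient condition-gradient parameters, see [generate_truth()].
#' @param seed integer master RNG seed (mandatory; all randomness derives
#'   from it).
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(site_code = "GR0000001",
                              habitat_code = "9560",
                              polygon = NULL,
                              protocol = NULL,
                              protocol_spec = list(),
                              n_expert_plots = 6,
                              n_nonexpert_plots = 30,
                              n_experts = 2,
                              expert = observer_model("expert"),
                              non_expert = observer_model("non_expert"),
                              gradient = list(),
                              seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (is.null(polygon)) {
    polygon <- habitat_polygon(cbind(c(0, 100, 100, 0), c(0, 0, 100, 100)))
  }
  stopifnot(n_expert_plots >= 1, n_nonexpert_plots >= 1, n_experts >= 1,
            inherits(expert, "observer_model"),
            inherits(non_expert, "observer_model"))
  structure(
    list(site_code = site_code, habitat_code = habitat_code,
         polygon = polygon, protocol = protocol,
         protocol_spec = protocol_spec,
         n_expert_plots = n_expert_plots,
         n_nonexpert_plots = n_nonexpert_plots,
         n_experts = n_experts,
         expert = expert, non_expert = non_expert,
         gradient = gradient, seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' Simulate a full expert / non-expert survey
#'
#' Composes the generator: builds (or reuses) the habitat protocol, places
#' expert and non-expert plots inside the patch according to each group's
#' edge-bias scale, draws the latent condition of every plot from the
#' edge-distance gradient, and thins it through each observer's detection
#' model. Expert plots are shared round-robin among the expert observer
#' ids; each non-expert plot gets its own observer id (non-experts record
#' one plot each). Fully deterministic given the config seed.
#'
#' @param config a [simulation_config()].
#' @return a [survey_dataset()]; the latent truths are attached as
#'   `attr(, "truths")` (a list named by plot id) for calibration studies.
#' @export
simulate_survey <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  sub <- sample.int(.Machine$integer.max,
                    4 + 2 * (config$n_expert_plots +
                             config$n_nonexpert_plots))
  protocol <- config$protocol
  if (is.null(protocol)) {
    protocol <- do.call(generate_protocol, c(
      config$protocol_spec,
      list(habitat_code = config$habitat_code, seed = sub[1])))
  }
  loc_exp <- sample_plot_locations(config$polygon, config$n_expert_plots,
                                   config$expert$edge_scale_lambda, sub[2])
  loc_non <- sample_plot_locations(config$polygon, config$n_nonexpert_plots,
                                   config$non_expert$edge_scale_lambda,
                                   sub[3])
  n_tot <- config$n_expert_plots + config$n_nonexpert_plots
  seeds_truth <- sub[3 + seq_len(n_tot)]
  seeds_obs <- sub[3 + n_tot + seq_len(n_tot)]

  plots <- vector("list", n_tot)
  truths <- vector("list", n_tot)
  for (i in seq_len(n_tot)) {
    is_exp <- i <= config$n_expert_plots
    loc <- if (is_exp) loc_exp[i, ] else loc_non[i - config$n_expert_plots, ]
    obs_model <- if (is_exp) config$expert else config$non_expert
    plot_id <- sprintf("%s_%s_%03d", config$habitat_code,
                       if (is_exp) "exp" else "non", i)
    observer_id <- if (is_exp) {
      sprintf("expert_%02d", (i - 1) %% config$n_experts + 1)
    } else {
      sprintf("citizen_%03d", i - config$n_expert_plots)
    }
    truths[[i]] <- generate_truth(loc, protocol, config$polygon,
                                  config$gradient, seeds_truth[i])
    plots[[i]] <- simulate_observation(truths[[i]], obs_model, protocol,
                                       plot_id, observer_id,
                                       seed = seeds_obs[i])
  }
  names(truths) <- vapply(plots, function(p) p$plot_id, character(1))
  ds <- survey_dataset(config$site_code, config$habitat_code, plots,
                       protocol)
  attr(ds, "truths") <- truths
  ds
}
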