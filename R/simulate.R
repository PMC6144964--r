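#' Scenario configuration for synthetic otolith-chemistry data
#'
#' Bundles everything the generator needs: the sampled sites (latitude and
#' per-stream sample sizes), per-site edge-chemistry medians and log-scale
#' spreads, the natal-source signatures and the source-to-site mixing
#' matrix, the origin-to-area connectivity matrix for adults, and the noise
#' model. All randomness downstream is fixed by the seed passed to the
#' generators.
#'
#' @param sites data.frame with columns `site`, `lat`, `n_ablation`,
#'   `n_whole`.
#' @param site_median matrix (site x element) of edge-chemistry medians on
#'   the measurement scale.
#' @param site_sdlog matrix (site x element) of log-scale standard
#'   deviations for edge draws.
#' @param source_mean,source_sd matrices (source x element): natal-source
#'   signatures on the measurement scale.
#' @param mixing matrix (source x site); each site's column gives the
#'   proportions of its settled fish originating from each natal source and
#'   must sum to 1.
#' @param connectivity matrix (origin site x adult area); each area's
#'   column is the probability distribution of origins for adults sampled
#'   there and must sum to 1.
#' @param w whole-otolith blend weight: whole = w * core-like +
#'   (1 - w) * edge-like on the linear scale. Default 0.3 (the whole
#'   otolith integrates the full juvenile period, dominated by
#'   post-settlement growth).
#' @param cv_log log-scale SD of multiplicative measurement noise added to
#'   whole-otolith and milled-core values. Default 0.1.
#' @param core_edge_offset named multiplier per element applied to
#'   core-like draws (temperature/ontogeny hook); default 1 for every
#'   element so natal-source means stay exactly as configured.
#' @param batch_offset log-scale additive offset applied to adult
#'   milled-core values (juvenile and adult solution runs are separate
#'   batches); default 0, i.e. no batch effect.
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(sites, site_median, site_sdlog,
                            source_mean, source_sd, mixing, connectivity,
                            w = 0.3, cv_log = 0.1,
                            core_edge_offset = NULL, batch_offset = 0) {
  stopifnot(is.data.frame(sites),
            all(c("site", "lat", "n_ablation", "n_whole") %in% names(sites)))
  if (any(abs(sites$lat) > 90)) stop("latitude out of range", call. = FALSE)
  elements <- colnames(site_median)
  if (is.null(elements)) stop("site_median needs element colnames", call. = FALSE)
  if (!identical(colnames(source_mean), elements) ||
      !identical(colnames(site_sdlog), elements) ||
      !identical(colnames(source_sd), elements))
    stop("element columns must agree across site and source tables",
         call. = FALSE)
  if (any(site_sdlog <= 0) || any(source_sd <= 0))
    stop("spreads must be > 0", call. = FALSE)
  if (any(site_median <= 0) || any(source_mean <= 0))
    stop("means must be > 0", call. = FALSE)
  if (max(abs(colSums(mixing) - 1)) > 1e-8)
    stop("mixing columns must sum to 1", call. = FALSE)
  if (max(abs(colSums(connectivity) - 1)) > 1e-8)
    stop("connectivity columns must sum to 1", call. = FALSE)
  if (!setequal(colnames(mixing), sites$site))
    stop("mixing columns must cover the sites", call. = FALSE)
  if (is.null(core_edge_offset))
    core_edge_offset <- stats::setNames(rep(1, length(elements)), elements)
  structure(list(sites = sites, site_median = site_median,
                 site_sdlog = site_sdlog, source_mean = source_mean,
                 source_sd = source_sd, mixing = mixing,
                 connectivity = connectivity, w = w, cv_log = cv_log,
                 core_edge_offset = core_edge_offset,
                 batch_offset = batch_offset,
                 elements = elements),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("<scenario_config> %d sites, %d natal sources, elements %s\n",
              nrow(x$sites), nrow(x$source_mean),
              paste(x$elements, collapse = ",")))
  invisible(x)
}

# lognormal parameterized by measurement-scale mean m and sd s
.lnorm_pars <- function(m, s) {
  sdlog2 <- log1p((s / m)^2)
  list(meanlog = log(m) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

#' Built-in simulation scenarios
#'
#' `study_default` emulates the North Sea study design: ten nursery sites
#' (SB, GB, GC, DA, TA, BU, ES, NS, FB, SH), 15 fish per site in the
#' ablation stream (none for the German coast, 135 total) and 43 per site
#' in the whole-otolith stream; four elements with a negative latitudinal
#' Mn gradient and a positive latitudinal Ba gradient, about a threefold
#' range in median Mn, Mg and Sr and 1.6x in Ba across sites; four natal
#' sources whose mean (SD) signatures are Mg 85.9 (23.4), Mn 5.2 (2.7),
#' Ba 4 (2.3), Sr 2031.4 (433.7) for source A and correspondingly for B-D;
#' and a mostly-diagonal origin-to-area connectivity with within-region
#' spillover. `north_south` is a six-site two-group design with a tunable
#' separation multiplier; `null_uniform` makes every site and source
#' identical (for type-I error and assignment-null checks).
#'
#' @param name one of `"study_default"`, `"north_south"`, `"null_uniform"`.
#' @param separation multiplier on the log-scale deviations of group means
#'   for `north_south`; 0 reduces it to `null_uniform`'s structure.
#' @return a [scenario_config()].
#' @export
scenario_preset <- function(name = c("study_default", "north_south",
                                     "null_uniform"),
                            separation = 1) {
  name <- match.arg(name)
  elements <- c("Mg", "Mn", "Ba", "Sr")
  if (name == "study_default") {
    sites <- data.frame(
      site = c("SB", "GB", "GC", "DA", "TA", "BU", "ES", "NS", "FB", "SH"),
      lat  = c(52.3, 54.1, 53.9, 55.5, 56.5, 57.6, 58.3, 58.9, 56.8, 60.3),
      stringsAsFactors = FALSE
    )
    sites$n_ablation <- ifelse(sites$site == "GC", 0L, 15L)
    sites$n_whole <- 43L
    # latitudinal gradients: Mn high in the south (3x range), Ba high in
    # the north (1.6x); Sr declines Shetland->Skagerrak and Tay->south;
    # Mg high on the eastern side (FB, DA)
    f <- (sites$lat - min(sites$lat)) / diff(range(sites$lat))
    mn <- 9.0 - f * 6.0
    ba <- 2.5 + f * 1.5
    sr <- c(SB = 900, GB = 1100, GC = 1000, DA = 1500, TA = 2400,
            BU = 1900, ES = 1300, NS = 1400, FB = 2200, SH = 2700)
    mg <- c(SB = 90, GB = 75, GC = 80, DA = 140, TA = 50,
            BU = 55, ES = 65, NS = 70, FB = 150, SH = 60)
    site_median <- cbind(Mg = unname(mg[sites$site]), Mn = mn,
                         Ba = ba, Sr = unname(sr[sites$site]))
    rownames(site_median) <- sites$site
    site_sdlog <- matrix(0.25, nrow(sites), length(elements),
                         dimnames = list(sites$site, elements))
    source_mean <- rbind(
      A = c(Mg = 85.9, Mn = 5.2, Ba = 4.0, Sr = 2031.4),
      B = c(Mg = 70.2, Mn = 6.1, Ba = 2.9, Sr = 1867.0),
      C = c(Mg = 66.0, Mn = 3.1, Ba = 2.8, Sr = 1474.5),
      D = c(Mg = 77.5, Mn = 3.6, Ba = 7.9, Sr = 2013.8)
    )
    source_sd <- rbind(
      A = c(Mg = 23.4, Mn = 2.7, Ba = 2.3, Sr = 433.7),
      B = c(Mg = 11.8, Mn = 3.3, Ba = 1.7, Sr = 497.3),
      C = c(Mg = 14.4, Mn = 1.6, Ba = 1.2, Sr = 222.3),
      D = c(Mg = 17.6, Mn = 4.5, Ba = 4.0, Sr = 429.0)
    )
    # source-to-site mixing: A dominates the Southern Bight and is absent
    # from German Bight and Fisher Bank; B feeds the central sites but not
    # the northern ones; C dominates the Skagerrak and reaches Fisher Bank;
    # D dominates the northern sites and is absent from the Southern Bight
    mixing <- rbind(
      A = c(SB = 0.85, GB = 0.00, GC = 0.20, DA = 0.20, TA = 0.20,
            BU = 0.15, ES = 0.05, NS = 0.05, FB = 0.00, SH = 0.00),
      B = c(SB = 0.15, GB = 0.70, GC = 0.60, DA = 0.50, TA = 0.60,
            BU = 0.55, ES = 0.15, NS = 0.05, FB = 0.00, SH = 0.00),
      C = c(SB = 0.00, GB = 0.25, GC = 0.20, DA = 0.20, TA = 0.15,
            BU = 0.20, ES = 0.60, NS = 0.55, FB = 0.40, SH = 0.25),
      D = c(SB = 0.00, GB = 0.05, GC = 0.00, DA = 0.10, TA = 0.05,
            BU = 0.10, ES = 0.20, NS = 0.35, FB = 0.60, SH = 0.75)
    )
    connectivity <- .regional_connectivity(sites$site, default_region_map(),
                                           self = 0.6)
    return(scenario_config(sites, site_median, site_sdlog,
                           source_mean, source_sd, mixing, connectivity))
  }
  if (name == "north_south") {
    sites <- data.frame(
      site = c("S1", "S2", "S3", "N1", "N2", "N3"),
      lat = c(52, 53, 54, 58, 59, 60),
      n_ablation = 15L, n_whole = 30L, stringsAsFactors = FALSE
    )
    base <- c(Mg = 75, Mn = 5, Ba = 3.5, Sr = 1800)
    dev <- c(Mg = 0.5, Mn = 0.6, Ba = -0.5, Sr = 0.4) * separation
    south <- base * exp(dev / 2)
    north <- base * exp(-dev / 2)
    site_median <- rbind(south, south, south, north, north, north)
    dimnames(site_median) <- list(sites$site, elements)
    site_sdlog <- matrix(0.2, 6, 4, dimnames = list(sites$site, elements))
    source_mean <- rbind(S = south, N = north)
    source_sd <- source_mean * 0.2
    mixing <- cbind(S1 = c(1, 0), S2 = c(1, 0), S3 = c(1, 0),
                    N1 = c(0, 1), N2 = c(0, 1), N3 = c(0, 1))
    rownames(mixing) <- c("S", "N")
    connectivity <- diag(6)
    dimnames(connectivity) <- list(sites$site, sites$site)
    return(scenario_config(sites, site_median, site_sdlog,
                           source_mean, source_sd, mixing, connectivity))
  }
  # null_uniform: no geographic or natal structure whatsoever
  sites <- data.frame(
    site = c("SB", "GB", "GC", "DA", "TA", "BU", "ES", "NS", "FB", "SH"),
    lat  = c(52.3, 54.1, 53.9, 55.5, 56.5, 57.6, 58.3, 58.9, 56.8, 60.3),
    n_ablation = 15L, n_whole = 43L, stringsAsFactors = FALSE
  )
  base <- c(Mg = 75, Mn = 5, Ba = 3.5, Sr = 1800)
  site_median <- matrix(rep(base, each = 10), 10, 4,
                        dimnames = list(sites$site, elements))
  site_sdlog <- matrix(0.25, 10, 4, dimnames = list(sites$site, elements))
  source_mean <- matrix(base, 1, 4, dimnames = list("A", elements))
  source_sd <- source_mean * 0.25
  mixing <- matrix(1, 1, 10, dimnames = list("A", sites$site))
  connectivity <- matrix(1 / 10, 10, 10,
                         dimnames = list(sites$site, sites$site))
  scenario_config(sites, site_median, site_sdlog,
                  source_mean, source_sd, mixing, connectivity)
}

# mostly-diagonal connectivity: each area draws `self` from its own site
# and the remainder equally from the other sites of its region
.regional_connectivity <- function(sites, rm, self = 0.6) {
  S <- length(sites)
  regions <- region_of(rm, sites)
  M <- matrix(0, S, S, dimnames = list(sites, sites))
  for (a in seq_len(S)) {
    peers <- setdiff(which(regions == regions[a]), a)
    M[a, a] <- if (length(peers)) self else 1
    if (length(peers)) M[peers, a] <- (1 - self) / length(peers)
  }
  M
}

#' Rescale natal-source separation
#'
#' Moves every source's log-mean away from (factor > 1) or toward the
#' element-wise grand log-mean, leaving SD-to-mean ratios unchanged. Used
#' to study how cluster recovery depends on source separability.
#'
#' @param cfg a [scenario_config()].
#' @param factor multiplier on log-scale deviations from the grand mean.
#' @return modified `scenario_config`.
#' @export
scale_source_separation <- function(cfg, factor) {
  lm <- log(cfg$source_mean)
  center <- colMeans(lm)
  lm <- sweep(sweep(lm, 2, center) * factor, 2, center, `+`)
  new_mean <- exp(lm)
  cfg$source_sd <- cfg$source_sd * (new_mean / cfg$source_mean)
  cfg$source_mean <- new_mean
  cfg
}

.draw_source_values <- function(cfg, k, n) {
  p <- length(cfg$elements)
  out <- matrix(0, n, p, dimnames = list(NULL, cfg$elements))
  for (j in seq_len(p)) {
    pars <- .lnorm_pars(cfg$source_mean[k, j], cfg$source_sd[k, j])
    out[, j] <- stats::rlnorm(n, pars$meanlog, pars$sdlog) *
      cfg$core_edge_offset[[cfg$elements[j]]]
  }
  out
}

.draw_site_values <- function(cfg, s, n) {
  p <- length(cfg$elements)
  out <- matrix(0, n, p, dimnames = list(NULL, cfg$elements))
  for (j in seq_len(p))
    out[, j] <- stats::rlnorm(n, log(cfg$site_median[s, j]),
                              cfg$site_sdlog[s, j])
  out
}

.meas_noise <- function(cfg, n, p) {
  matrix(exp(stats::rnorm(n * p, 0, cfg$cv_log)), n, p)
}

#' Generate the juvenile datasets of a scenario
#'
#' For every site, draws each fish's natal source from the site's mixing
#' column, then generates: near-core values from the source signature, edge
#' values from the site's settlement chemistry, and a whole-otolith value
#' blending a core-like and an edge-like draw (`w * core + (1 - w) * edge`
#' on the linear scale) with multiplicative measurement noise. Fish in the
#' ablation stream carry all three zones; the remaining whole-otolith fish
#' carry only `whole`. All values are log-normal, hence strictly positive.
#'
#' @param cfg a [scenario_config()].
#' @param seed integer seed; the same seed reproduces the dataset exactly.
#' @return an `otolith_dataset`; attribute `truth` is a data.frame
#'   (`fish_id`, `site`, `source`) with each fish's true natal source.
#' @export
generate_juveniles <- function(cfg, seed = 1) {
  set.seed(seed)
  p <- length(cfg$elements)
  sources <- rownames(cfg$source_mean)
  recs <- list(); truth <- list()
  for (i in seq_len(nrow(cfg$sites))) {
    s <- cfg$sites$site[i]
    n_abl <- cfg$sites$n_ablation[i]
    n_tot <- max(cfg$sites$n_whole[i], n_abl)
    if (n_tot == 0) next
    ids <- sprintf("J-%s-%03d", s, seq_len(n_tot))
    src <- sources[sample.int(length(sources), n_tot, replace = TRUE,
                              prob = cfg$mixing[, s])]
    core_like <- do.call(rbind, lapply(seq_len(n_tot), function(f)
      .draw_source_values(cfg, src[f], 1)))
    edge_like <- .draw_site_values(cfg, s, n_tot)
    whole <- (cfg$w * core_like + (1 - cfg$w) * edge_like) *
      .meas_noise(cfg, n_tot, p)
    meta <- function(id, zone) data.frame(
      fish_id = id, life_stage = "juvenile", zone = zone, site = s,
      lat = cfg$sites$lat[i], lon = 0, year_class = 2007L, batch = "sim",
      stringsAsFactors = FALSE)
    if (n_abl > 0) {
      abl <- seq_len(n_abl)
      recs[[length(recs) + 1L]] <-
        cbind(meta(ids[abl], "near_core"), core_like[abl, , drop = FALSE])
      recs[[length(recs) + 1L]] <-
        cbind(meta(ids[abl], "edge"), edge_like[abl, , drop = FALSE])
    }
    wh <- seq_len(min(cfg$sites$n_whole[i], n_tot))
    if (length(wh))
      recs[[length(recs) + 1L]] <-
        cbind(meta(ids[wh], "whole"), whole[wh, , drop = FALSE])
    truth[[length(truth) + 1L]] <-
      data.frame(fish_id = ids, site = s, source = src,
                 stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, recs)
  ds <- otolith_dataset(df, element_panel(cfg$elements, units = "ug_g"),
                        provenance = "synthetic scenario")
  attr(ds, "truth") <- do.call(rbind, truth)
  ds
}

#' Generate adult milled-core datasets with known origins
#'
#' Each adult sampled in an area draws its true origin site from that
#' area's connectivity column, then its milled-core chemistry from the
#' origin site's whole-otolith generative process (source draw blended with
#' an edge-like draw, plus measurement noise), optionally shifted by the
#' adult batch offset on the log scale.
#'
#' @param cfg a [scenario_config()].
#' @param n_per_area adults per sampling area (recycled over areas).
#' @param seed integer seed.
#' @param areas sampling-area labels; default the scenario's site codes
#'   (adults are sampled on spawning grounds labelled like the sites).
#' @return an `otolith_dataset` of `milled_core` records whose `site`
#'   column holds the sampling area; attribute `truth` is a data.frame
#'   (`fish_id`, `area`, `origin`, `source`).
#' @export
generate_adults <- function(cfg, n_per_area = 45, seed = 1,
                            areas = colnames(cfg$connectivity)) {
  set.seed(seed + 1L)
  missing_areas <- setdiff(areas, colnames(cfg$connectivity))
  if (length(missing_areas))
    stop("areas absent from connectivity: ",
         paste(missing_areas, collapse = ", "), call. = FALSE)
  n_per_area <- rep_len(n_per_area, length(areas))
  p <- length(cfg$elements)
  origins_all <- rownames(cfg$connectivity)
  sources <- rownames(cfg$source_mean)
  recs <- list(); truth <- list()
  for (a in seq_along(areas)) {
    area <- areas[a]; n <- n_per_area[a]
    if (n == 0) next
    ids <- sprintf("A-%s-%03d", area, seq_len(n))
    org <- origins_all[sample.int(length(origins_all), n, replace = TRUE,
                                  prob = cfg$connectivity[, area])]
    src <- vapply(org, function(o)
      sources[sample.int(length(sources), 1, prob = cfg$mixing[, o])],
      character(1))
    core_like <- do.call(rbind, lapply(seq_len(n), function(f)
      .draw_source_values(cfg, src[f], 1)))
    edge_like <- do.call(rbind, lapply(seq_len(n), function(f)
      .draw_site_values(cfg, org[f], 1)))
    vals <- (cfg$w * core_like + (1 - cfg$w) * edge_like) *
      .meas_noise(cfg, n, p) * exp(cfg$batch_offset)
    recs[[length(recs) + 1L]] <- cbind(
      data.frame(fish_id = ids, life_stage = "adult", zone = "milled_core",
                 site = area, lat = NA_real_, lon = NA_real_,
                 year_class = 2007L, batch = "sim-adult",
                 stringsAsFactors = FALSE),
      vals)
    truth[[length(truth) + 1L]] <-
      data.frame(fish_id = ids, area = area, origin = unname(org),
                 source = unname(src), stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, recs)
  ds <- otolith_dataset(df, element_panel(cfg$elements, units = "ug_g"),
                        provenance = "synthetic scenario (adults)")
  attr(ds, "truth") <- do.call(rbind, truth)
  ds
}
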