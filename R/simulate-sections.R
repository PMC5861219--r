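#' Describe a planted co-expression module
#'
#' A planted module is a set of genes sharing a zone-peaked expression
#' archetype. One member is the designated hub: it carries the module
#' archetype with reduced noise plus a cross-module coupling component so
#' that it also correlates with the other planted modules and acts as a
#' bridge in the inferred network. A subset of members can follow the
#' negated archetype (anticorrelated members), producing negative edges.
#'
#' @param hub_gene Gene id of the designated hub (must be a member).
#' @param member_genes Character vector of member gene ids (includes hub).
#' @param peak_zone Zone in which the archetype peaks, one of
#'   [zone_levels()].
#' @param anticorrelated_members Subset of `member_genes` (never the hub)
#'   following the negated archetype.
#' @param coupling Coupling strength of members to the archetype, in (0, 1].
#' @return A `planted_module` list.
#' @export
planted_module <- function(hub_gene, member_genes, peak_zone,
                           anticorrelated_members = character(),
                           coupling = 0.9) {
  if (!hub_gene %in% member_genes) stop("hub_gene must be a member")
  if (!peak_zone %in% ZONES) stop("unknown zone label: ", peak_zone)
  if (!all(anticorrelated_members %in% member_genes))
    stop("anticorrelated_members must be a subset of member_genes")
  if (hub_gene %in% anticorrelated_members)
    stop("the hub follows the positive archetype")
  if (coupling <= 0 || coupling > 1) stop("coupling must be in (0, 1]")
  structure(list(hub_gene = hub_gene, member_genes = member_genes,
                 peak_zone = peak_zone,
                 anticorrelated_members = anticorrelated_members,
                 coupling = coupling),
            class = "planted_module")
}

#' Configuration for the section-series simulator
#'
#' Defines a multi-tree stem cryosection experiment: each tree contributes a
#' longitudinal series of sections spanning the four developmental zones in
#' order (phloem/cambium, expanding xylem, secondary cell wall formation,
#' cell death). Planted modules follow smooth Gaussian-bump archetypes
#' peaking in one zone; background genes are independent noise around a
#' per-gene baseline. Values are on a VST-like scale.
#'
#' @param seed Integer RNG seed; a fixed seed reproduces the data exactly.
#' @param n_genes Total number of genes.
#' @param n_trees Number of trees (default 4).
#' @param sections_per_zone Named integer vector, sections per zone per tree
#'   in zone order. Defaults reflect the relative widths of the zones in a
#'   typical aspen cryosection series: P/C 5, Ex 4, SCW 9, CD 7.
#' @param modules List of [planted_module()]s; `NULL` plants the default
#'   three well-separated 20-gene modules (peaks in P/C, SCW and CD).
#' @param noise_sd Gaussian noise standard deviation (expression units).
#' @param baseline_mean,baseline_sd Mean and spread of per-gene baselines.
#' @param amplitude Peak height of the archetype bump above baseline.
#' @param hub_cross_coupling Strength of the hub's coupling to the other
#'   modules' archetypes, in \[0, 1).
#' @param hub_noise_sd Noise level of hub genes (default `noise_sd / 3`).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L, n_genes = 300L, n_trees = 4L,
                              sections_per_zone = c("P/C" = 5L, "Ex" = 4L,
                                                    "SCW" = 9L, "CD" = 7L),
                              modules = NULL, noise_sd = 0.3,
                              baseline_mean = 6, baseline_sd = 1,
                              amplitude = 3, hub_cross_coupling = 0.15,
                              hub_noise_sd = noise_sd / 3) {
  stopifnot(n_genes >= 1, n_trees >= 1, noise_sd >= 0, amplitude > 0,
            hub_cross_coupling >= 0, hub_cross_coupling < 1)
  if (!identical(names(sections_per_zone), ZONES))
    stop("sections_per_zone must be named by the ordered zones: ",
         paste(ZONES, collapse = ", "))
  if (any(sections_per_zone < 1)) stop("every zone needs at least 1 section")
  if (is.null(modules)) {
    genes <- default_gene_ids(n_genes)
    modules <- default_planted_modules(genes)
  }
  sizes <- vapply(modules, function(m) length(m$member_genes), integer(1))
  if (sum(sizes) > n_genes) stop("module sizes exceed n_genes")
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 n_trees = as.integer(n_trees),
                 sections_per_zone = sections_per_zone, modules = modules,
                 noise_sd = noise_sd, baseline_mean = baseline_mean,
                 baseline_sd = baseline_sd, amplitude = amplitude,
                 hub_cross_coupling = hub_cross_coupling,
                 hub_noise_sd = hub_noise_sd),
            class = "simulation_config")
}

default_gene_ids <- function(n) sprintf("G%04d", seq_len(n))

# three 20-gene modules peaking in well-separated zones; the first member of
# each is the designated hub
default_planted_modules <- function(genes) {
  if (length(genes) < 60) stop("default modules need at least 60 genes")
  peaks <- c("P/C", "SCW", "CD")
  lapply(1:3, function(i) {
    members <- genes[((i - 1) * 20 + 1):(i * 20)]
    planted_module(hub_gene = members[1], member_genes = members,
                   peak_zone = peaks[i])
  })
}

# smooth bump over positions 1..n_pos centered in the peak zone, width tied
# to the zone's extent so neighbouring zones overlap only in the tails
zone_archetype <- function(peak_zone, sections_per_zone) {
  ends <- cumsum(sections_per_zone)
  starts <- ends - sections_per_zone + 1
  i <- match(peak_zone, ZONES)
  center <- (starts[i] + ends[i]) / 2
  width <- sections_per_zone[i] / 2
  pos <- seq_len(sum(sections_per_zone))
  exp(-0.5 * ((pos - center) / width)^2)
}

#' Simulate a stem section expression series with planted structure
#'
#' Generates a genes x sections matrix per [simulation_config()]: module
#' members follow `coupling * archetype` plus Gaussian noise, anticorrelated
#' members the negated archetype, hub genes additionally couple to the other
#' modules' archetypes (making them network bridges), and background genes
#' are independent noise around their baseline. The archetype is a Gaussian
#' bump over the section positions of each tree, repeated across trees with
#' independent noise.
#'
#' @param config A [simulation_config()].
#' @return A list with elements `series` (a [section_series()]) and `truth`
#'   (module membership, hub ids, anticorrelated members, peak zones and
#'   background gene ids).
#' @export
generate_section_series <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  spz <- config$sections_per_zone
  n_pos <- sum(spz)
  genes <- default_gene_ids(config$n_genes)
  for (m in config$modules) {
    if (!all(m$member_genes %in% genes))
      stop("module genes must be among the generated gene ids")
  }
  zone_of_pos <- rep(ZONES, times = spz)
  meta <- do.call(rbind, lapply(seq_len(config$n_trees), function(tr) {
    data.frame(section = sprintf("T%d_S%02d", tr, seq_len(n_pos)),
               tree = sprintf("T%d", tr), zone = zone_of_pos,
               position = seq_len(n_pos), stringsAsFactors = FALSE)
  }))

  bumps <- vapply(ZONES, zone_archetype, numeric(n_pos),
                  sections_per_zone = spz)
  bump_all <- do.call(rbind, replicate(config$n_trees, bumps,
                                       simplify = FALSE))  # sections x zones

  values <- withr::with_seed(config$seed, {
    n_sec <- nrow(meta)
    v <- matrix(0, config$n_genes, n_sec,
                dimnames = list(genes, meta$section))
    baselines <- rnorm(config$n_genes, config$baseline_mean,
                       config$baseline_sd)
    names(baselines) <- genes
    other_peaks <- lapply(seq_along(config$modules), function(i) {
      vapply(config$modules[-i], function(m) m$peak_zone, character(1))
    })
    for (g in genes)
      v[g, ] <- baselines[g] + rnorm(n_sec, 0, config$noise_sd)
    for (i in seq_along(config$modules)) {
      m <- config$modules[[i]]
      own <- config$amplitude * bump_all[, m$peak_zone]
      cross <- if (length(other_peaks[[i]]))
        config$amplitude * config$hub_cross_coupling *
          rowSums(bump_all[, other_peaks[[i]], drop = FALSE])
      else rep(0, n_sec)
      for (g in m$member_genes) {
        s <- if (g %in% m$anticorrelated_members) -1 else 1
        if (g == m$hub_gene) {
          # the hub carries the clean archetype (full coupling, low noise)
          # so that every member correlates more strongly with it than with
          # any other member; modules come out hub-centered
          v[g, ] <- baselines[g] + own + cross +
            rnorm(n_sec, 0, config$hub_noise_sd)
        } else {
          v[g, ] <- baselines[g] + s * m$coupling * own +
            rnorm(n_sec, 0, config$noise_sd)
        }
      }
    }
    v
  })

  truth <- list(
    modules = lapply(config$modules, function(m) {
      list(hub = m$hub_gene, members = m$member_genes,
           anticorrelated = m$anticorrelated_members,
           peak_zone = m$peak_zone)
    }),
    hubs = vapply(config$modules, function(m) m$hub_gene, character(1)),
    background = setdiff(genes, unlist(lapply(config$modules,
                                              function(m) m$member_genes)))
  )
  list(series = section_series(values, meta), truth = truth)
}

#' Write / read simulation ground truth as JSON
#'
#' @param truth Ground-truth list as returned by the generators.
#' @param path File path.
#' @return `read_ground_truth` returns the ground-truth list.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
}
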