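# Download-free synthetic generators: knowledge bases with planted
# statistical structure emulating averaged multimodal connectivity plus
# region-pair differential-expression counts, and localized-expression
# tables with a planted hotspot.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Synthetic knowledge-base configuration
#'
#' Defines the study conditions the generator emulates: a fully connected
#' set of brain regions with symmetric structural connectivity in [0, 1],
#' functional connectivity in [-1, 1] drawn around a monotone transform of
#' the structural value (so that structural connectivity above 0.4 yields
#' essentially only positive correlations), and sub-region-level DEG counts
#' realised with a target rank correlation against functional connectivity.
#' Two regions are planted: a hub with maximal weighted degree, and an
#' exception region ("putamen"-like) combining high structural connectivity
#' with high differential expression against the global trend.
#'
#' @param n_regions number of regions; the default 21 yields 210 connection
#'   pairs, the scale at which trend recovery is assessed.
#' @param coords_per_region measured coordinates per region.
#' @param seed RNG seed; generation is deterministic per seed.
#' @param hub_region index of the planted high-degree region.
#' @param exception_region index of the planted high-structural/high-DEG
#'   region.
#' @param deg_conn_association target Spearman correlation between
#'   functional connectivity and DEG count, in [-1, 0].
#' @param subregions_per_region is-a children per region term; DEG links
#'   live at this finer level, so the cross-modal join requires ontology
#'   descent.
#' @return A \code{synth_config} list.
#' @export
synth_config <- function(n_regions = 21, coords_per_region = 1, seed = 1,
                         hub_region = 1, exception_region = 2,
                         deg_conn_association = -0.6,
                         subregions_per_region = 2) {
  if (n_regions < 3)
    ckb_stop("need at least 3 regions", "ckb_validation_error")
  if (hub_region > n_regions || exception_region > n_regions ||
      hub_region < 1 || exception_region < 1)
    ckb_stop("hub/exception indices must be region indices",
             "ckb_validation_error")
  if (hub_region == exception_region)
    ckb_stop("hub and exception regions must differ", "ckb_validation_error")
  if (deg_conn_association < -1 || deg_conn_association > 0)
    ckb_stop("deg_conn_association must lie in [-1, 0]",
             "ckb_validation_error")
  structure(list(n_regions = n_regions,
                 coords_per_region = coords_per_region, seed = seed,
                 hub_region = hub_region,
                 exception_region = exception_region,
                 deg_conn_association = deg_conn_association,
                 subregions_per_region = subregions_per_region),
            class = "synth_config")
}

# inverse-CDF truncated normal (no boundary atoms)
rtnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd); phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

# pair-level draws; regions indexed 1..n, pairs i<j
generate_matrices <- function(config) {
  n <- config$n_regions
  hub <- config$hub_region; exc <- config$exception_region
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- pairs[, 1]; j <- pairs[, 2]
  m <- length(i)
  # structural: beta-distributed background, boosted hub, uniform strong
  # exception edges (all >= 0.15 so the exception survives struct >= 0.1)
  s <- stats::rbeta(m, 2, 5) * 0.6
  is_hub <- (i == hub | j == hub)
  is_exc_any <- (i == exc | j == exc)
  is_exc <- is_exc_any & !is_hub
  s[is_hub] <- pmin(0.95, s[is_hub] + 0.35)
  s[is_exc] <- stats::runif(sum(is_exc), 0.15, 0.65)
  # functional: truncated normal around a monotone transform of structural;
  # mean -0.25 + 1.4 s keeps s > 0.4 essentially all-positive. Exception
  # edges get weak positive correlations (strong anatomical links whose
  # activities barely correlate), the putamen phenomenology.
  f <- rtnorm(m, mean = -0.25 + 1.4 * s, sd = 0.12, lo = -1, hi = 1)
  f[is_exc_any] <- stats::runif(sum(is_exc_any), 0.02, 0.33)
  # DEG: rounded log-normal scaled by (1 - functional). The log-scale noise
  # sd follows the attenuation identity sd(noise) = sd(u) * sqrt(1/r^2 - 1)
  # with u = log(1 - f), but r must be inflated before use: truncating u,
  # rounding, capping counts above 200 at strong structural edges and the
  # anti-trend exception edges all attenuate the realized rank correlation.
  # The linear calibration below (realized ~= 0.97 r_eff - 0.29, fitted by
  # simulation at 210 pairs) maps the configured association onto the
  # effective log-scale correlation that realizes it.
  u <- log(pmax(1 - f, 0.02))
  r <- abs(config$deg_conn_association)
  r_eff <- min(0.995, 1.05 * r + 0.32)
  noise_sd <- stats::sd(u[!is_exc_any]) * sqrt(1 / r_eff^2 - 1)
  deg <- exp(log(25) + u + stats::rnorm(m, 0, noise_sd))
  # exception edges carry putamen-scale counts; elsewhere, counts above 200
  # co-occur only with weak structural connectivity
  deg[is_exc_any] <- stats::runif(sum(is_exc_any), 550, 950)
  cap <- !is_exc_any & s >= 0.1
  deg[cap] <- pmin(deg[cap], 200)
  deg <- round(deg)
  S <- matrix(0, n, n); F <- matrix(0, n, n); D <- matrix(NA_real_, n, n)
  CAP <- matrix(FALSE, n, n)
  S[cbind(i, j)] <- s; S[cbind(j, i)] <- s
  F[cbind(i, j)] <- f; F[cbind(j, i)] <- f
  D[cbind(i, j)] <- deg; D[cbind(j, i)] <- deg
  CAP[cbind(i, j)] <- cap; CAP[cbind(j, i)] <- cap
  region_labels <- sprintf("region %02d", seq_len(n))
  coords <- data.frame(
    region = rep(seq_len(n), each = config$coords_per_region),
    x = round(stats::runif(n * config$coords_per_region, -70, 70), 1),
    y = round(stats::runif(n * config$coords_per_region, -100, 70), 1),
    z = round(stats::runif(n * config$coords_per_region, -45, 75), 1))
  coords$identifier <- sprintf("c%03d", seq_len(nrow(coords)))
  coords$label <- region_labels[coords$region]
  list(structural = S, functional = F, deg = D, capped = CAP,
       region_labels = region_labels, coords = coords)
}

#' Generate a synthetic knowledge base
#'
#' Builds a complete, self-contained knowledge base from a
#' \code{\link{synth_config}}: measured coordinates, a flat atlas, a
#' two-level ontology (root, region terms, sub-region terms), brain
#' structures and mappings, imported symmetric structural and functional
#' connectivity experiments, and DEG links between sub-region structures
#' drawn so that the rank correlation between functional connectivity and
#' DEG count approximates the configured association. Deterministic per
#' seed.
#'
#' @param config a \code{\link{synth_config}}.
#' @return A knowledge base; the drawn matrices are attached as attribute
#'   \code{"truth"} (structural, functional, deg, coords, region_labels).
#' @export
generate_kb <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, {
    mats <- generate_matrices(config)
    n <- config$n_regions
    nsub <- config$subregions_per_region
    kb <- kb_new(brain_model = TRUE)

    atlas_tab <- data.frame(entry_id = mats$coords$identifier,
                            label = mats$coords$label,
                            stringsAsFactors = FALSE)
    kb_load_flat_atlas(kb, "synthatlas", atlas_tab)

    region_terms <- sprintf("t%03d", seq_len(n))
    sub_terms <- as.vector(t(outer(seq_len(n), seq_len(nsub),
                                   function(i, k) sprintf("t%03d_s%d", i, k))))
    terms <- data.frame(
      term_id = c("root", region_terms, sub_terms),
      name = c("brain", mats$region_labels,
               paste0(rep(mats$region_labels, each = nsub), " sub ",
                      rep(seq_len(nsub), n))),
      stringsAsFactors = FALSE)
    edges <- rbind(
      data.frame(child_id = region_terms, parent_id = "root",
                 stringsAsFactors = FALSE),
      data.frame(child_id = sub_terms,
                 parent_id = rep(region_terms, each = nsub),
                 stringsAsFactors = FALSE))
    kb_load_ontology(kb, "synthonto", terms, edges)

    region_structs <- sprintf("structure %02d", seq_len(n))
    sub_structs <- paste0(rep(region_structs, each = nsub), " sub ",
                          rep(seq_len(nsub), n))
    kb_add_brain_structures(kb, c(region_structs, sub_structs))

    # connectivity import first, so coordinates exist before parcellation
    ci_s <- connectivity_input(mats$structural, mats$coords$label,
                               mats$coords[, c("identifier", "x", "y", "z")],
                               "DTI", "normalized fiber density")
    ci_f <- connectivity_input(mats$functional, mats$coords$label,
                               mats$coords[, c("identifier", "x", "y", "z")],
                               "rs-fMRI", "normalized correlation value")
    import_connectivity_matrix(kb, ci_s, "synthetic DTI avg")
    import_connectivity_matrix(kb, ci_f, "synthetic fMRI avg")

    kb_parcellate_coordinates(kb,
      data.frame(coord_id = mats$coords$identifier,
                 entry_id = mats$coords$identifier,
                 stringsAsFactors = FALSE), "synthatlas")
    mapping <- rbind(
      data.frame(atlas = "synthatlas",
                 entry_id = mats$coords$identifier,
                 structure_name = region_structs[mats$coords$region],
                 ontology = NA_character_, term_id = NA_character_,
                 stringsAsFactors = FALSE),
      data.frame(atlas = "", entry_id = NA_character_,
                 structure_name = region_structs,
                 ontology = "synthonto", term_id = region_terms,
                 stringsAsFactors = FALSE),
      data.frame(atlas = "", entry_id = NA_character_,
                 structure_name = sub_structs,
                 ontology = "synthonto", term_id = sub_terms,
                 stringsAsFactors = FALSE))
    kb_register_brain_mapping(kb, mapping)

    # DEG links at sub-region level: per region pair, one count per
    # sub-structure pair, jittered around the pair-level draw
    rows <- list()
    for (a in seq_len(n - 1)) for (b in (a + 1):n) {
      d <- mats$deg[a, b]
      for (ka in seq_len(nsub)) for (kb_ in seq_len(nsub)) {
        jit <- max(0, round(d * stats::runif(1, 0.85, 1.15)))
        # capped pairs stay capped after jitter, so sub-pair averages above
        # 200 remain exclusive to the exception region
        if (mats$capped[a, b]) jit <- min(jit, 200)
        rows[[length(rows) + 1L]] <- data.frame(
          structure_a = sub_structs[(a - 1) * nsub + ka],
          structure_b = sub_structs[(b - 1) * nsub + kb_],
          deg_count = jit, stringsAsFactors = FALSE)
      }
    }
    import_deg(kb, do.call(rbind, rows))
    attr(kb, "truth") <- mats
    kb
  })
}

#' Generate a localized gene-expression table with a planted hotspot
#'
#' Emulates microarray sampling across the knowledge base's brain
#' structures: two probes per (gene, structure, donor). At the hotspot
#' structure, the listed genes are expressed above the localization
#' threshold (values in (8.3, 10.5), PACall 1); elsewhere values are
#' background (normal around 6.5) and any draw exceeding 8 has its PACall
#' flag cleared, as a signal not above background. Deterministic per seed.
#'
#' @param kb a knowledge base whose "brain structure" instances define the
#'   sampled locations.
#' @param hotspot_structure structure name; must exist in the kb.
#' @param genes character vector of hotspot genes (may be empty for a
#'   background-only table).
#' @param seed RNG seed.
#' @param donor donor identifier.
#' @param background_genes always-sampled background genes.
#' @return data.frame in the expression-import layout (donor, structure_id,
#'   probe_id, gene_symbol, expression, pacall).
#' @export
generate_expression_fixture <- function(kb, hotspot_structure, genes,
                                        seed = 1, donor = "synth1",
                                        background_genes = c("actb")) {
  structs <- vapply(kb_instances(kb, "brain structure"), ref_id, "")
  if (!hotspot_structure %in% structs)
    ckb_stop(sprintf("unknown hotspot structure '%s'", hotspot_structure),
             "ckb_lookup_error")
  all_genes <- unique(c(genes, background_genes))
  with_seed(seed, {
    rows <- list()
    for (g in all_genes) for (st in structs) for (p in 1:2) {
      hot <- st == hotspot_structure && g %in% genes
      v <- if (hot) stats::runif(1, 8.3, 10.5)
           else stats::rnorm(1, 6.5, 0.8)
      pac <- if (hot) 1 else ifelse(v > 8, 0, stats::rbinom(1, 1, 0.6))
      rows[[length(rows) + 1L]] <- data.frame(
        donor = donor, structure_id = st,
        probe_id = sprintf("%s_p%d", g, p), gene_symbol = g,
        expression = round(v, 4), pacall = pac, stringsAsFactors = FALSE)
    }
    if (!length(rows))
      return(data.frame(donor = character(), structure_id = character(),
                        probe_id = character(), gene_symbol = character(),
                        expression = numeric(), pacall = numeric(),
                        stringsAsFactors = FALSE))
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
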