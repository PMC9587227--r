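#' Replicated scenario comparison on synthetic landscapes
#'
#' Runs the full pipeline (landscape, life zones, PGD, binarized
#' distributions) on a series of seeded synthetic landscapes and compares
#' how well the top landscape fraction represents each taxon x PGD piece
#' under two feature configurations: distributions alone (`"SDM"`) and
#' distributions subdivided by PGD (`"SDMxPGD"`). For each replicate the
#' minimum and mean per-PGD retained proportion at top fraction `f` are
#' reported for both scenarios, both ranked over the same land mask.
#'
#' @param seeds Integer vector; one replicate per seed.
#' @param n_rows,n_cols,n_taxa Synthetic-landscape size (see [sim_config()]).
#' @param f Top landscape fraction at which representation is evaluated.
#' @return A tibble with one row per seed: `min_sdm`, `min_cross`,
#'   `mean_sdm`, `mean_cross`, and the logicals `min_ok` / `mean_ok`
#'   (subdivided scenario at least as good).
#' @export
scenario_improvement_stats <- function(seeds, n_rows = 25L, n_cols = 25L,
                                       n_taxa = 6L, f = 0.2) {
  purrr::map_dfr(seeds, function(s) {
    cfg <- sim_config(seed = s, n_rows = n_rows, n_cols = n_cols,
                      n_taxa = n_taxa, n_ssi = 0L)
    land <- simulate_landscape(cfg)
    lz <- classify_lifezones(land$climate)
    pgd <- subdivide_lifezones(
      lz, divider_set(land$dividers,
                      cycled_assignment(lz, names(land$dividers))))
    sim <- simulate_taxa(cfg, pgd)
    sdm <- purrr::imap(sim$suitability, function(suit, tx) {
      pts <- points_to_cells(sim$presences[[tx]], pgd$zones$spec)
      binarize_sdm(suit, pts, "p10")$grid
    })
    mask_land <- pgd$zones
    per_pgd <- function(scenario) {
      fs <- build_scenario(scenario, sdm, pgd = pgd)
      rk <- caz_rank(fs, mask = mask_land)
      top <- top_fraction(rk, f)
      props <- purrr::map(sdm, function(g)
        pgd_area_representation(top, g, pgd)$proportion)
      unlist(props)
    }
    p_sdm <- per_pgd("SDM")
    p_cross <- per_pgd("SDMxPGD")
    tibble::tibble(
      seed = s,
      min_sdm = min(p_sdm), min_cross = min(p_cross),
      mean_sdm = mean(p_sdm), mean_cross = mean(p_cross),
      min_ok = min(p_cross) >= min(p_sdm),
      mean_ok = mean(p_cross) >= mean(p_sdm)
    )
  })
}
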