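#' Run the full synthetic end-to-end demonstration
#'
#' Generates one ground-truth scene, renders the four synthetic sensor
#' products, extracts change with each product's own recipe (trajectory
#' segmentation, stable-map categorical change, period-mean fractional
#' change, annual-loss accumulation), aggregates areas nationally and
#' provincially, builds loss/gain agreement maps and the provincial
#' correlation matrices, and returns every table. With `out_dir` set, each
#' table is also written as CSV together with the run configuration, so two
#' runs with the same seed produce identical files.
#'
#' @param config A [run_config()].
#' @param out_dir Optional directory for CSV output.
#' @return A named list: `national` (per-dataset loss/gain/net areas and
#'   coverage percentages), `provincial` (per-dataset province tables),
#'   `agreement_loss`/`agreement_gain` (agreement maps),
#'   `composition_loss`/`composition_gain`, `correlations` (per metric),
#'   `truth` (the scene), `products` (the rendered inputs), and
#'   `change_maps`.
#' @export
run_report <- function(config = run_config(), out_dir = NULL) {
  grid <- config$grid
  seed <- config$seed
  scene <- make_truth(grid, mix = config$mix, seed = seed)
  cover0 <- true_cover(scene)

  nbr <- render_nbr(scene, sigma = config$noise$sigma_nbr, seed = seed + 1L)
  lc <- render_lc(scene, flip_prob = config$noise$flip_prob_lc,
                  seed = seed + 2L)
  vcf <- render_vcf(scene, sigma_pct = config$noise$sigma_vcf_pct,
                    seed = seed + 3L)
  gfc <- render_gfc(scene)

  # forest mask for the detector: baseline cover at/above 40%
  mask <- cube_layer(cover0, grid$year_start) >= 0.4
  cm_nbr <- detect_changes(nbr, params = config$detector, mask = mask)

  lc_t1 <- stable_class_map(lc, config$windows$t1)
  lc_t2 <- stable_class_map(lc, config$windows$t2)
  cm_lc <- categorical_change(lc_t1, lc_t2,
                              forest_definition("class_set"), grid)

  vcf500 <- annual_cube(
    aggregate_cube(vcf$values, 2L), grid, kind = "percent")
  win1 <- seq(grid$year_start, grid$year_start + 2L)
  win2 <- seq(grid$year_end - 2L, grid$year_end)
  fc_vcf <- fractional_change(period_mean_cover(vcf500, win1),
                              period_mean_cover(vcf500, win2), grid)

  factor_gfc <- gfc$grid$rows %/% grid$rows
  loss_fine <- accumulate_annual_loss(gfc$loss)
  fc_gfc_loss <- aggregate_fraction(loss_fine, factor_gfc)
  fc_gfc_gain <- aggregate_fraction(gfc$gain, factor_gfc)
  fc_gfc <- structure(list(delta = fc_gfc_gain - fc_gfc_loss, grid = grid),
                      class = "fraction_change")

  change_maps <- list(nbr = cm_nbr, lc = cm_lc, vcf = fc_vcf, gfc = fc_gfc)
  land_area <- grid$rows * grid$cols * pixel_area_km2(grid)
  if (!is.null(config$land_area_km2)) land_area <- config$land_area_km2

  national <- purrr::imap(change_maps, function(m, nm) {
    a <- if (inherits(m, "change_map")) binary_change_area(m, grid) else
      fractional_change_area(m, grid)
    tibble::tibble(dataset = nm, loss_km2 = a$loss_km2,
                   gain_km2 = a$gain_km2,
                   net_km2 = a$gain_km2 - a$loss_km2) |>
      dplyr::mutate(loss_pct = coverage_percent(.data$loss_km2, land_area),
                    gain_pct = coverage_percent(.data$gain_km2, land_area),
                    net_pct = coverage_percent(.data$net_km2, land_area))
  }) |> dplyr::bind_rows()

  prov <- render_provinces(grid, 2L, 2L)
  provincial <- purrr::imap(change_maps, function(m, nm) {
    provincial_aggregate(m, prov$raster, prov$table, grid) |>
      dplyr::mutate(dataset = nm, .before = 1)
  }) |> dplyr::bind_rows()

  flags <- function(direction) {
    lapply(change_maps, to_binary_change, direction = direction)
  }
  fl <- flags("loss"); fg <- flags("gain")
  agree_loss <- agreement_count(fl, "loss")
  agree_gain <- agreement_count(fg, "gain")

  cor_input <- function(metric) {
    provincial |>
      dplyr::filter(!is.na(.data$province_id)) |>
      dplyr::transmute(dataset = .data$dataset,
                       province_id = .data$province_id,
                       value = .data[[metric]])
  }
  correlations <- list(
    loss = correlation_matrix(cor_input("loss_pct")),
    gain = correlation_matrix(cor_input("gain_pct")),
    net = correlation_matrix(cor_input("net_pct"))
  )

  out <- list(
    national = national, provincial = provincial,
    agreement_loss = agree_loss, agreement_gain = agree_gain,
    composition_loss = agreement_composition(agree_loss, fl),
    composition_gain = agreement_composition(agree_gain, fg),
    correlations = correlations,
    truth = scene,
    products = list(nbr = nbr, lc = lc, vcf = vcf, gfc = gfc),
    change_maps = change_maps,
    provinces = prov
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(national, file.path(out_dir, "national.csv"),
                     row.names = FALSE)
    utils::write.csv(provincial, file.path(out_dir, "provincial.csv"),
                     row.names = FALSE)
    utils::write.csv(out$composition_loss,
                     file.path(out_dir, "composition_loss.csv"),
                     row.names = FALSE)
    utils::write.csv(out$composition_gain,
                     file.path(out_dir, "composition_gain.csv"),
                     row.names = FALSE)
    for (m in names(correlations)) {
      utils::write.csv(tidy(correlations[[m]]),
                       file.path(out_dir, paste0("correlation_", m, ".csv")),
                       row.names = FALSE)
    }
    write_run_config(config, file.path(out_dir, "run_config.json"))
  }
  out
}

# block-average an array layer by layer
aggregate_cube <- function(values, factor) {
  n_years <- dim(values)[3]
  out <- array(NA_real_, dim = c(dim(values)[1] %/% factor,
                                 dim(values)[2] %/% factor, n_years))
  for (t in seq_len(n_years)) {
    out[, , t] <- aggregate_average(values[, , t, drop = TRUE], factor)
  }
  out
}
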