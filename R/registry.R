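# The fixed 156-feature registry of regional morphometric measures.
#
# The measures follow the Desikan-Killiany cortical parcellation (34 regions
# per hemisphere, thickness and surface area), two hemispheric summary
# measures per hemisphere (mean cortical thickness, total surface area), and
# 16 subcortical volumes (8 structures per hemisphere). The exact per-study
# naming of such tables is not standardized across consortia; this registry
# is a faithful reconstruction using the atlas region names and documents
# the pairing used for ipsi/contra relabeling and asymmetry indices.

.dk_regions <- c(
  "bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
  "entorhinal", "fusiform", "inferiorparietal", "inferiortemporal",
  "isthmuscingulate", "lateraloccipital", "lateralorbitofrontal", "lingual",
  "medialorbitofrontal", "middletemporal", "parahippocampal", "paracentral",
  "parsopercularis", "parsorbitalis", "parstriangularis", "pericalcarine",
  "postcentral", "posteriorcingulate", "precentral", "precuneus",
  "rostralanteriorcingulate", "rostralmiddlefrontal", "superiorfrontal",
  "superiorparietal", "superiortemporal", "supramarginal", "frontalpole",
  "temporalpole", "transversetemporal", "insula"
)

.subcortical <- c(
  "thalamus", "caudate", "putamen", "pallidum",
  "hippocampus", "amygdala", "accumbens", "lateralventricle"
)

#' Registry of the 156 regional morphometric features
#'
#' Returns the ordered feature table the whole pipeline is keyed on:
#' 68 regional cortical thickness measures, 68 regional surface areas,
#' 2 hemispheric mean thicknesses, 2 hemispheric total surface areas, and
#' 16 subcortical volumes. Each feature carries its hemisphere, measure kind,
#' region label, the pair identifier linking its left/right counterparts
#' (78 pairs in all), and the expected direction of disease-related change
#' (`-1` = decrease; `+1` = increase, used for the lateral ventricles).
#'
#' @return data.frame with columns `name`, `hemisphere`, `kind`, `region`,
#'   `pair_id`, `direction`; exactly 156 rows.
#' @export
#' @examples
#' reg <- feature_registry()
#' nrow(reg)                 # 156
#' length(unique(reg$pair_id))  # 78
feature_registry <- function() {
  rows <- list()
  for (hemi in c("lh", "rh")) {
    side <- if (hemi == "lh") "left" else "right"
    rows[[length(rows) + 1L]] <- data.frame(
      name = paste0(hemi, "_", .dk_regions, "_thick"),
      hemisphere = side, kind = "thickness", region = .dk_regions,
      pair_id = paste0(.dk_regions, "_thick"), direction = -1
    )
  }
  for (hemi in c("lh", "rh")) {
    side <- if (hemi == "lh") "left" else "right"
    rows[[length(rows) + 1L]] <- data.frame(
      name = paste0(hemi, "_", .dk_regions, "_surf"),
      hemisphere = side, kind = "surface_area", region = .dk_regions,
      pair_id = paste0(.dk_regions, "_surf"), direction = -1
    )
  }
  rows[[length(rows) + 1L]] <- data.frame(
    name = c("lh_mean_thick", "rh_mean_thick"),
    hemisphere = c("left", "right"), kind = "thickness",
    region = "hemisphere_mean", pair_id = "hemisphere_mean_thick",
    direction = -1
  )
  rows[[length(rows) + 1L]] <- data.frame(
    name = c("lh_total_surf", "rh_total_surf"),
    hemisphere = c("left", "right"), kind = "surface_area",
    region = "hemisphere_total", pair_id = "hemisphere_total_surf",
    direction = -1
  )
  for (hemi in c("lh", "rh")) {
    side <- if (hemi == "lh") "left" else "right"
    rows[[length(rows) + 1L]] <- data.frame(
      name = paste0(hemi, "_", .subcortical, "_vol"),
      hemisphere = side, kind = "volume", region = .subcortical,
      pair_id = paste0(.subcortical, "_vol"),
      direction = ifelse(.subcortical == "lateralventricle", 1, -1)
    )
  }
  reg <- do.call(rbind, rows)
  rownames(reg) <- NULL
  stopifnot(nrow(reg) == 156L, length(unique(reg$pair_id)) == 78L)
  reg
}

#' Write the feature registry to CSV
#'
#' Machine-readable copy of [feature_registry()] for audit alongside run
#' artifacts.
#'
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_registry <- function(path) {
  utils::write.csv(feature_registry(), path, row.names = FALSE)
  invisible(path)
}

# Baseline per-feature population mean and SD used by the simulator;
# rough magnitudes typical of adult FreeSurfer morphometry (mm, mm^2, mm^3).
.feature_baselines <- function(reg = feature_registry()) {
  mu <- numeric(nrow(reg))
  sd <- numeric(nrow(reg))
  vol_mu <- c(thalamus = 7500, caudate = 3800, putamen = 5500, pallidum = 1800,
              hippocampus = 4000, amygdala = 1700, accumbens = 600,
              lateralventricle = 8000)
  vol_sd <- c(thalamus = 700, caudate = 450, putamen = 600, pallidum = 250,
              hippocampus = 450, amygdala = 250, accumbens = 120,
              lateralventricle = 2600)
  for (i in seq_len(nrow(reg))) {
    k <- reg$kind[i]; r <- reg$region[i]
    if (k == "thickness") {
      if (r == "hemisphere_mean") { mu[i] <- 2.5; sd[i] <- 0.10 }
      else { mu[i] <- 2.5; sd[i] <- 0.15 }
    } else if (k == "surface_area") {
      if (r == "hemisphere_total") { mu[i] <- 85000; sd[i] <- 8000 }
      else { mu[i] <- 2500; sd[i] <- 350 }
    } else {
      mu[i] <- vol_mu[[r]]; sd[i] <- vol_sd[[r]]
    }
  }
  data.frame(name = reg$name, mu = mu, sd = sd)
}
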