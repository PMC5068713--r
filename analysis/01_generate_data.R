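#!/usr/bin/env Rscript
# Stage 1: generate the synthetic raw data for the downstream analyses.
#
# No microscopy measurements are distributed with this project, so every
# downstream stage runs on synthetic tables whose statistical structure
# mirrors the study system: per-chromosome arm-length measurements for the
# four species' reference karyotypes (at the study's plate counts), and two
# aneuploidy-polymorphic laboratory lines with DV1- and HUB1-like karyotype
# frequencies.

library(karyopoly)

seed <- 20160915L %% 10000L   # fixed: all stages are reproducible end to end
out <- "results/synthetic"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

## reference plate sets for morphometry (study plate counts per species)
ref <- list(lignano = list(n = 50, karyo = c(2, 6)),
            sp8     = list(n = 35, karyo = c(4, 6)),
            spirale = list(n = 20, karyo = c(0, 6)),
            hystrix = list(n = 20, karyo = c(0, 6)))
for (sp in names(ref)) {
  params <- species_morphometry_params(sp)
  plates <- do.call(rbind, lapply(seq_len(ref[[sp]]$n), function(i) {
    generate_plate(ref[[sp]]$karyo, params,
                   specimen_id = sprintf("%s_W%02d", sp, (i + 1L) %/% 2L),
                   plate_id = sprintf("%s_P%02d", sp, i),
                   seed = seed + i)
  }))
  write_karyo_table(plates, file.path(out, paste0("measurements_", sp, ".csv")))
  cat(sprintf("%-8s %3d plates, %4d chromosomes\n", sp, ref[[sp]]$n, nrow(plates)))
}

## two aneuploidy-polymorphic lines (category frequencies as observed in the
## inbred lines; small abnormal fraction; no mosaicism, as observed)
lines <- list(
  synDV1  = population_spec(c(0.119, 0.575, 0.269, 0.037), n_specimens = 500,
                            plates_per_specimen = 10, mosaic_rate = 0),
  synHUB1 = population_spec(c(0.131, 0.526, 0.307, 0.036), n_specimens = 500,
                            plates_per_specimen = 10, mosaic_rate = 0))
for (nm in names(lines)) {
  set <- generate_specimen_set(lines[[nm]], seed = seed + match(nm, names(lines)))
  write_karyo_table(set$measurements, file.path(out, paste0(nm, "_measurements.csv")))
  write_karyo_table(set$plate_counts, file.path(out, paste0(nm, "_plate_counts.csv")))
  write_karyo_table(set$specimens, file.path(out, paste0(nm, "_truth.csv")))
  cat(sprintf("%s: %d specimens x %d plates\n", nm,
              lines[[nm]]$n_specimens, lines[[nm]]$plates_per_specimen))
}

## provenance sidecar
prov <- list(seed = seed,
             category_probs = lapply(lines, `[[`, "category_probs"),
             note = "synthetic data; condensation sdlog 0.12, noise sd 0.05 um")
writeLines(jsonlite::toJSON(prov, auto_unbox = TRUE, pretty = TRUE),
           file.path(out, "generation_params.json"))
cat("done; tables under", out, "\n")
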