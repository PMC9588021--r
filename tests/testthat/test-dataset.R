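test_that("configuration validation lists offending keys", {
  expect_error(preset_config("spruce", bond_freqs = c("beta-O-4" = -1)),
               "bond_freqs")
  expect_error(preset_config("spruce", nonsense_key = 1), "unknown configuration key")
  expect_error(preset_config("spruce", dp_values = c(2, 5)), "dp_values")
  bad <- preset_config("spruce")
  bad$wood_type <- "Q-type"
  expect_error(validate_config(bad), "wood_type")
})

test_that("YAML configs load with presets, overrides and DP range shorthand", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("preset: birch",
               "dp_values: 3-25",
               "structures_per_dp: 5",
               "seed: 99"), f)
  cfg <- load_config(f)
  expect_equal(cfg$wood_type, "SG-type")
  expect_equal(cfg$sg_ratio, 1.8)
  expect_length(cfg$dp_values, 23)
  expect_equal(cfg$structures_per_dp, 5)
  # spruce preset is pure G with softwood linkage anchors
  f2 <- withr::local_tempfile(fileext = ".yaml")
  writeLines("preset: spruce", f2)
  cfg2 <- load_config(f2)
  expect_equal(cfg2$sg_ratio, 0)
  expect_equal(cfg2$wood_type, "G-type")
})

test_that("DP-dependent bond-frequency targets interpolate and normalize", {
  cfg <- preset_config("spruce")
  f3 <- bond_freqs_at(cfg, 3)
  f20 <- bond_freqs_at(cfg, 20)
  f25 <- bond_freqs_at(cfg, 25)
  expect_equal(sum(f3), 1, tolerance = 1e-12)
  expect_equal(f20, f25)
  expect_lt(f3[["beta-O-4"]], f20[["beta-O-4"]])
  f10 <- bond_freqs_at(cfg, 10)
  expect_true(f3[["beta-O-4"]] < f10[["beta-O-4"]] &&
                f10[["beta-O-4"]] < f20[["beta-O-4"]])
})

test_that("generate_dataset produces a consistent catalog with on-disk files", {
  tdir <- withr::local_tempdir()
  cfg <- preset_config("birch", dp_values = c(5L, 6L), structures_per_dp = 4L,
                       seed = 123L, output_dir = tdir,
                       formats = c("json", "csv", "mol"), mol_dims = 2,
                       verbose = FALSE)
  ds <- generate_dataset(cfg)
  expect_equal(sum(ds$summary$accepted), 8)
  ids <- unlist(lapply(ds$catalog, names))
  expect_false(any(duplicated(ids)))
  expect_true(file.exists(file.path(tdir, "catalog.json")))
  payload <- read_json_catalog(file.path(tdir, "catalog.json"))
  # every catalog entry references files that exist and carries the core fields
  for (dp in names(payload$structures))
    for (e in payload$structures[[dp]]) {
      expect_true(file.exists(file.path(tdir, e$files$csv)))
      expect_true(file.exists(file.path(tdir, e$files$mol)))
      expect_true(nzchar(e$smiles))
      expect_equal(as.integer(dp), e$dp)
      expect_equal(sum(unlist(e$bond_counts)), e$dp - 1)
      # CSV re-reads to a graph of the right DP
      m <- read_matrices_csv(file.path(tdir, e$files$csv))
      expect_length(m$labels, e$dp)
    }
  # coupling rules are exported for auditability
  expect_true(length(payload$coupling_rules) > 0)
  # SMILES are unique across the dataset
  smis <- unlist(lapply(payload$structures, function(d) vapply(d, `[[`, "", "smiles")))
  expect_false(any(duplicated(smis)))
})

test_that("empty quota yields an empty but valid catalog", {
  tdir <- withr::local_tempdir()
  cfg <- preset_config("spruce", dp_values = 5L, structures_per_dp = 0L,
                       seed = 1L, output_dir = tdir, formats = "json",
                       verbose = FALSE)
  ds <- generate_dataset(cfg)
  expect_equal(sum(ds$summary$accepted), 0)
  payload <- read_json_catalog(ds$catalog_path)
  expect_length(payload$structures[["5"]], 0)
})

test_that("duplicate lg_id is an integrity error", {
  entries <- list("5" = list(a1 = list(lg_id = "a1")),
                  "6" = list(a1 = list(lg_id = "a1")))
  expect_error(write_json_catalog(entries, withr::local_tempfile()), "integrity error")
})

test_that("identical seeds give byte-identical catalogs; order of dp_values is immaterial", {
  t1 <- withr::local_tempdir(); t2 <- withr::local_tempdir(); t3 <- withr::local_tempdir()
  mk <- function(dir, dps) {
    cfg <- preset_config("birch", dp_values = dps, structures_per_dp = 3L,
                         seed = 77L, output_dir = dir, formats = "json",
                         verbose = FALSE)
    generate_dataset(cfg)
  }
  mk(t1, c(5L, 7L)); mk(t2, c(5L, 7L)); mk(t3, c(7L, 5L))
  c1 <- readLines(file.path(t1, "catalog.json"))
  c2 <- readLines(file.path(t2, "catalog.json"))
  expect_identical(c1, c2)
  # per-DP RNG streams: same structures regardless of dp order
  p1 <- read_json_catalog(file.path(t1, "catalog.json"))$structures
  p3 <- read_json_catalog(file.path(t3, "catalog.json"))$structures
  expect_identical(p1[["5"]], p3[["5"]])
  expect_identical(p1[["7"]], p3[["7"]])
})
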