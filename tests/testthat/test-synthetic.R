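test_that("specimen tables are deterministic and respect their config", {
  cfg <- sim_config(n_taxa = 50, seed = 7)
  t1 <- make_specimen_table(cfg)
  t2 <- make_specimen_table(cfg)
  expect_identical(t1, t2)
  t3 <- make_specimen_table(sim_config(n_taxa = 50, seed = 8))
  expect_false(identical(t1, t3))

  expect_equal(nrow(t1), 50L)
  expect_true(all(t1$fad_ma >= t1$lad_ma))
  expect_true(all(t1$clade %in% c("nonamniote", "synapsid", "sauropsid")))
  expect_true(all(t1$diet %in% c("herbivore", "nonherbivore")))
  aw <- cfg$age_window
  expect_true(all(t1$fad_ma <= aw[1] & t1$lad_ma >= aw[2]))
})

test_that("clade proportions are recovered within multinomial sampling error", {
  p <- c(0.4, 0.4, 0.2)
  cfg <- sim_config(n_taxa = 1000, clade_proportions = p, seed = 1)
  tab <- make_specimen_table(cfg)
  obs <- as.numeric(table(factor(tab$clade, levels = c("nonamniote",
                                                       "synapsid",
                                                       "sauropsid")))) / 1000
  se <- sqrt(p * (1 - p) / 1000)
  expect_true(all(abs(obs - p) <= 3 * se))
})

test_that("invalid configurations are rejected with the offending field named", {
  expect_error(sim_config(age_window = c(250, 300)), "age_window")
  expect_error(sim_config(clade_proportions = c(0.5, 0.5, 0.5)),
               "clade_proportions")
  expect_error(sim_config(herbivore_fraction = 1.4), "herbivore_fraction")
  expect_error(sim_config(n_taxa = 0), "n_taxa")
  cfg <- sim_config(n_taxa = 10)
  cfg$trait_sds[1, 1] <- 0
  expect_error(validate_sim_config(cfg), "trait_sds")
})

test_that("trait matrices carry the configured group structure", {
  cfg <- sim_config(n_taxa = 40, trait_group = "diet", seed = 11)
  meta <- make_specimen_table(cfg)
  m1 <- make_trait_matrix(meta, cfg)
  expect_identical(m1, make_trait_matrix(meta, cfg))
  expect_identical(dim(m1), c(40L, 9L))
  expect_identical(colnames(m1), trait_names())

  ## degenerate noise returns the exact group means
  cfg0 <- cfg
  cfg0$trait_sds[] <- 1e-300
  m0 <- make_trait_matrix(meta, cfg0)
  herb <- meta$diet == "herbivore"
  for (g in c("herbivore", "nonherbivore")) {
    rows <- m0[meta$diet == g, , drop = FALSE]
    expect_equal(unname(rows),
                 matrix(cfg$trait_means[g, ], nrow(rows), 9, byrow = TRUE),
                 tolerance = 1e-12)
  }

  ## a taxon whose group has no mean row is an error
  meta2 <- meta; meta2$diet[1] <- "herbivore"
  cfg2 <- cfg; rownames(cfg2$trait_means) <- c("carnivore", "nonherbivore")
  expect_error(make_trait_matrix(meta, cfg2), "missing from trait_means")
})

test_that("injected variance inflation is recoverable and monotone in the multiplier", {
  meta <- two_group_metadata(200)
  rejections <- sapply(c(1, 2, 4), function(m) {
    hits <- 0L
    for (s in 1:100) {
      cfg <- sim_config(n_taxa = 400, trait_group = "diet", seed = s)
      cfg$variance_multipliers[] <- 1
      cfg$variance_multipliers["herbivore", 1] <- m
      cfg$trait_means["herbivore", ] <- cfg$trait_means["nonherbivore", ]
      tm <- make_trait_matrix(meta, cfg)
      lv <- levene_test(tm[, 1], meta$diet)
      if (lv$p_value < 0.01) hits <- hits + 1L
    }
    hits
  })
  expect_true(all(diff(rejections) >= 0))
  expect_lt(rejections[1], 20)      # near-nominal under the null
  expect_gte(rejections[3], 95)     # 4x inflation detected almost always
})

test_that("parametric jaw outlines are simple, CCW and anterior-first", {
  p <- shape_params()
  o <- make_jaw_outline(p, 660)
  expect_s3_class(o, "outline")
  expect_equal(nrow(o), 660L)
  expect_gt(outline_area(o), 0)                  # counter-clockwise
  expect_equal(as.numeric(o[1, ]), c(p$length, 0))  # starts at anterior tip
  ## a joint sunk far below the tooth row cannot be rendered
  expect_error(make_jaw_outline(shape_params(articular_offset = -1)),
               "self-intersecting")
})

test_that("raising the coronoid raises the outline's maximum aspect ratio", {
  heights <- seq(0, 3, length.out = 7)   # up to 0.3 * length
  ars <- vapply(heights, function(h) {
    o <- make_jaw_outline(shape_params(coronoid_height = h), 400)
    diff(range(o[, 2])) / diff(range(o[, 1]))
  }, numeric(1))
  expect_true(all(diff(ars) > 0))
})

test_that("landmark construction matches its defining geometry", {
  p <- shape_params(length = 10, insertion_position = 0.2,
                    symphysis_length = 2, articular_offset = 0)
  lm <- make_landmarks(p)
  expect_equal(sqrt(sum((lm$insertion - lm$joint)^2)), 2.0)
  expect_equal(sqrt(sum((lm$symphysis_posterior - lm$anterior_tip)^2)), 2.0)
})

test_that("traits computed from generated landmarks equal the closed-form values", {
  set.seed(42)
  for (i in 1:100) {
    p <- random_shape_params()
    gt <- ground_truth_traits(p)
    ct <- compute_traits(make_landmarks(p), depth_profile_from_params(p))
    expect_lt(max(abs(gt - ct)), 1e-9)
  }
})

test_that("closed-form trait values honour the simple special cases", {
  gt <- ground_truth_traits(shape_params(length = 10, insertion_position = 0.2,
                                         articular_offset = 1e-12))
  expect_equal(unname(gt["anterior_ma"]), 0.2, tolerance = 1e-9)
  gt2 <- ground_truth_traits(shape_params(toothrow_span = c(0.1, 0.6),
                                          articular_offset = 0))
  expect_equal(unname(gt2["rel_toothrow"]), 0.5, tolerance = 1e-12)
})

test_that("shape sets and dataset writing are deterministic and complete", {
  cfg <- sim_config(n_taxa = 12, seed = 5)
  meta <- make_specimen_table(cfg)
  s1 <- make_shape_set(meta, cfg, n_points = 120)
  s2 <- make_shape_set(meta, cfg, n_points = 120)
  expect_identical(s1$params, s2$params)
  expect_identical(names(s1$outlines), meta$taxon_id)

  dir <- withr::local_tempdir()
  res <- write_synthetic_dataset(cfg, dir)
  expect_true(file.exists(file.path(dir, "metadata.csv")))
  expect_true(file.exists(file.path(dir, "landmarks.csv")))
  expect_equal(length(list.files(file.path(dir, "outlines"))), 12L)
  back <- read_outline(file.path(dir, "outlines",
                                 paste0(meta$taxon_id[1], ".txt")),
                       view = "lateral")
  orig <- res$shapes$outlines[[meta$taxon_id[1]]]
  expect_equal(as.matrix(back), as.matrix(orig), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("rasterised silhouettes reproduce the source outline", {
  o <- make_jaw_outline(shape_params(), 400)
  mask <- write_silhouette(o, width = 300)
  traced <- suppressWarnings(extract_outline(mask))
  ## areas agree up to pixelisation error (~perimeter/2 pixels)
  xy <- as.matrix(o)
  sc <- (300 - 16) / diff(range(xy[, 1]))
  expect_equal(outline_area(traced), outline_area(o) * sc^2,
               tolerance = 0.02)
})
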