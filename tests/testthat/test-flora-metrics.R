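test_that("hybridization propensity follows the pairwise-combination formula", {
  expect_equal(hybridization_propensity(0, 5), 0)
  expect_equal(hybridization_propensity(3, 5), 30)   # denominator 5*4/2 = 10
  expect_equal(hybridization_propensity(6, 4), 100)  # all 6 pairs hybridize
  expect_error(hybridization_propensity(1, 1), "n < 2")
  expect_error(hybridization_propensity(-1, 5), "nonnegative")
})

test_that("hybrid ratio divides hybrids by nonhybrid species", {
  expect_equal(hybrid_ratio(0, 7), 0)
  expect_equal(hybrid_ratio(3, 5), 0.6)
  expect_equal(hybrid_ratio(1.5, 10), 0.15)  # half-integer H carried exactly
  expect_error(hybrid_ratio(1, 0), "n < 1")
})

test_that("ratio and propensity obey the algebraic identity H/n = HP (n-1)/200", {
  set.seed(11)
  H <- runif(200, 0, 50)
  n <- sample(2:400, 200, replace = TRUE)
  expect_equal(hybrid_ratio(H, n),
               hybridization_propensity(H, n) * (n - 1) / 200,
               tolerance = 1e-12)
})

test_that("unspecified multiple-hybrid records resolve to max(2, 0.2 n)", {
  expect_equal(resolve_unspecified_hybrids(5), 2)
  expect_equal(resolve_unspecified_hybrids(10), 2)   # boundary 0.2 n = 2
  expect_equal(resolve_unspecified_hybrids(30), 6)
  expect_error(resolve_unspecified_hybrids(0), ">= 1")
})

test_that("genus aggregation sums counts across floras with half-weighted intergenerics", {
  rec <- toy_flora_records()
  gs <- aggregate_genus(rec)
  carex <- gs[gs$taxon == "Carex", ]
  expect_equal(carex$n, 6)  # 3 + 3 over two floras
  expect_equal(carex$H, 2)
  expect_equal(carex$propensity, 100 * 2 / (6 * 5 / 2))
  salix <- gs[gs$taxon == "Salix", ]
  expect_equal(salix$H, 2.5)  # one intergeneric half contributes 0.5
  # permutation invariance over flora record order
  gs2 <- aggregate_genus(rec[sample(nrow(rec)), ])
  expect_equal(gs2[order(gs2$taxon), ], gs[order(gs$taxon), ],
               ignore_attr = TRUE)
})

test_that("total H is conserved under the intergeneric splitting rule", {
  rec <- toy_flora_records()
  gs <- aggregate_genus(rec)
  expect_equal(sum(gs$H),
               sum(rec$n_intrageneric_hybrids) +
                 0.5 * sum(rec$n_intergeneric_hybrid_halves))
})

test_that("unspecified-multiple flags are resolved per record before summation", {
  rec <- toy_flora_records()
  rec$unspecified_multiple[rec$genus == "Rosa"] <- TRUE
  rec$n_intrageneric_hybrids[rec$genus == "Rosa"] <- 0
  gs <- aggregate_genus(rec)
  expect_equal(gs$H[gs$taxon == "Rosa"], 2)  # max(2, 0.2 * 5)
})

test_that("record validation enforces the table contract", {
  rec <- toy_flora_records()
  bad <- rbind(rec, rec[1, ])
  expect_error(validate_flora_records(bad), "duplicate")
  rec2 <- rec; rec2$n_nonhybrid[1] <- -1
  expect_error(validate_flora_records(rec2), "nonnegative")
  rec3 <- rec; rec3$n_intergeneric_hybrid_halves[1] <- 0.3
  expect_error(validate_flora_records(rec3), "steps of 0.5")
  rec4 <- rec[, -4]
  expect_error(validate_flora_records(rec4), "missing columns")
})

test_that("single-species single-flora genera with no hybrids are excluded", {
  rec <- toy_flora_records()
  gs <- aggregate_genus(rec)
  out <- apply_exclusions(gs, rec)
  expect_false("Lemna" %in% out$taxon)  # n = 1, one flora, H = 0
  expect_true("Poa" %in% out$taxon)     # n = 2: retained
  expect_equal(nrow(out), nrow(gs) - 1)
  out2 <- apply_exclusions(gs, rec, drop_taxa = "Poa")
  expect_false("Poa" %in% out2$taxon)
})

test_that("family metrics are species-weighted means of genus metrics", {
  gs <- data.frame(taxon = c("g1", "g2", "g3"), level = "genus",
                   family = c("F1", "F1", "F2"), n = c(5, 15, 4),
                   H = c(1.5, 0, 1), n_floras = 1,
                   propensity = c(30, 0, NA), ratio = c(0.6, 0.1, 0.25),
                   stringsAsFactors = FALSE)
  fam <- aggregate_family(gs)
  f1 <- fam[fam$taxon == "F1", ]
  expect_equal(f1$propensity, (30 * 5 + 0 * 15) / 20)
  expect_equal(f1$ratio, (0.6 * 5 + 0.1 * 15) / 20)
  expect_equal(f1$n, 20)
  expect_equal(f1$H, 1.5)
  # single-genus family: metrics equal the genus metrics
  expect_equal(fam[fam$taxon == "F2", "ratio"], 0.25)
  # weighted means stay inside the component range
  expect_true(f1$propensity >= 0 && f1$propensity <= 30)
  # unmapped genus errors by name
  expect_error(aggregate_family(gs, genus_to_family = c(g1 = "F1", g2 = "F1")),
               "g3")
})

test_that("equal-weight family means emerge from equal genus sizes", {
  gs <- data.frame(taxon = c("a", "b"), level = "genus", family = "F",
                   n = c(5, 5), H = c(3, 0.5), n_floras = 1,
                   propensity = c(30, 5), ratio = c(0.6, 0.1),
                   stringsAsFactors = FALSE)
  expect_equal(aggregate_family(gs)$ratio, 0.35)
})

test_that("log transform uses ln(x + offset) and rejects zero with no offset", {
  s <- data.frame(propensity = c(0, 30), ratio = c(0, 0.6))
  out <- log_transform_metrics(s)
  expect_equal(out$log_propensity, c(0, log(31)))
  expect_equal(out$log_ratio, c(0, log(1.6)))
  expect_error(log_transform_metrics(s, offset_propensity = 0), "offset")
  # monotone in the metric
  expect_true(all(diff(out$log_propensity[order(s$propensity)]) >= 0))
})
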