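# brute-force per-gene oracle shared by the selector tests
oracle_atlas <- function(v, groups, target, fc, ethr, ncomp) {
  comp <- setdiff(unique(groups), target)
  sel <- character(0)
  for (g in rownames(v)) {
    npass <- sum(sapply(comp, function(cg)
      mean(v[g, groups == target]) - mean(v[g, groups == cg]) > fc))
    e <- log2(sum(2^v[g, ]))
    if (npass >= ncomp && e > ethr) sel <- c(sel, g)
  }
  sel
}

test_that("atlas selector equals exhaustive per-gene checking and excludes
           flat genes", {
  fx <- simulate_assembly_fixture(seed = 11)
  for (i in 1:2) {
    m <- fx$atlas[[i]]; cfg <- fx$atlas_cfg[[i]]
    got <- atlas_select(m, cfg)
    want <- oracle_atlas(as.matrix(m$values), m$metadata$group,
                         cfg$target_group, cfg$log2fc_threshold,
                         cfg$expr_threshold, cfg$min_comparisons)
    expect_setequal(got, want)
  }
  # a gene identical across all groups has log2FC = 0 everywhere
  v <- matrix(5, 3, 6, dimnames = list(paste0("g", 1:3), paste0("s", 1:6)))
  m <- toy_log_matrix(v, rep(c("stem", "a", "b"), each = 2),
                      "log2_microarray")
  expect_length(atlas_select(m, selector_config(0.05, 3, 1, "stem")), 0)
  expect_error(atlas_select(m, selector_config(0.05, 3, 1, "nope")),
               "unknown target")
})

test_that("time-series selector recovers planted decay genes and rejects
           rising or flat genes", {
  fx <- simulate_assembly_fixture(seed = 12)
  want <- c(fx$planted, fx$decoys$ts_only)
  for (m in fx$timeseries) {
    got <- timeseries_select(m, fx$ts_cfg)
    expect_setequal(got, want)
  }
  # rising gene: higher at the last timepoint -> excluded by sign
  v <- matrix(c(2, 2, 6, 6), 1, 4,
              dimnames = list("up", paste0("s", 1:4)))
  m <- toy_log_matrix(v, rep("L", 4), "log2_microarray",
                      extra = data.frame(timepoint = c(0, 0, 336, 336)))
  expect_length(timeseries_select(m, selector_config(0.05, 0)), 0)
  expect_error(timeseries_select(
    toy_log_matrix(v, rep("L", 4), "log2_microarray"),
    selector_config(0.05, 0)), "timepoint")
})

test_that("knockdown selector takes the union over experiments and applies
           both thresholds", {
  fx <- simulate_assembly_fixture(seed = 13)
  got <- knockdown_select(fx$knockdown, fx$kd_cfg)
  expect_setequal(got, c(fx$planted, fx$decoys$kd_only))
  # passing in exactly one experiment is enough
  one <- knockdown_select(fx$knockdown[1], fx$kd_cfg)
  expect_setequal(got, one)
  # high fold-change but low E -> excluded
  v <- matrix(c(-4, -4, -8, -8), 1, 4,
              dimnames = list("lowe", paste0("s", 1:4)))
  m <- toy_log_matrix(v, rep(c("control", "knockdown"), each = 2),
                      "log2_microarray")
  expect_length(knockdown_select(list(m), selector_config(0.05, 3)), 0)
  expect_error(knockdown_select(list(), selector_config(0.05, 3)), "empty")
})

test_that("selectors are monotone in thresholds", {
  fx <- simulate_assembly_fixture(seed = 14)
  m <- fx$atlas[[1]]; cfg <- fx$atlas_cfg[[1]]
  base <- atlas_select(m, cfg)
  for (d in c(0.5, 1, 2.5)) {
    tighter <- selector_config(cfg$log2fc_threshold + d,
                               cfg$expr_threshold + d,
                               cfg$min_comparisons, cfg$target_group)
    expect_true(all(atlas_select(m, tighter) %in% base))
  }
})

test_that("assembly matches brute-force set algebra on random sets", {
  set.seed(21)
  universe <- sprintf("G%03d", 1:200)
  for (rep in 1:10) {
    lists <- lapply(1:4, function(i) sample(universe, sample(30:80, 1)))
    curated <- sample(universe, 8)
    ts <- sample(universe, 10); pr <- sample(universe, 12)
    cc <- sample(universe, 6)
    got <- tryCatch(
      assemble_stemness(lists, curated, ts, pr, cc)$genes,
      error = function(e) character(0))
    inter <- Reduce(intersect, lists)
    want <- setdiff(union(inter, curated), c(ts, pr, cc))
    expect_setequal(got, want)
  }
})

test_that("assembled signature never intersects the exclusion sets and the
           intersection is order-invariant", {
  fx <- simulate_assembly_fixture(seed = 22)
  lists <- c(lapply(1:2, function(i) atlas_select(fx$atlas[[i]],
                                                  fx$atlas_cfg[[i]])),
             lapply(fx$timeseries, timeseries_select, cfg = fx$ts_cfg),
             list(knockdown_select(fx$knockdown, fx$kd_cfg)))
  prolif <- c(fx$planted[1], "EXTRA1") # overlaps the planted set
  sig <- assemble_stemness(lists, curated = "CUR1",
                           proliferation = prolif)
  expect_length(intersect(sig$genes, prolif), 0)
  expect_setequal(sig$genes, c(setdiff(fx$planted, prolif), "CUR1"))
  sig2 <- assemble_stemness(rev(lists), curated = "CUR1",
                            proliferation = prolif)
  expect_setequal(sig$genes, sig2$genes)
  # curated subset of the intersection adds nothing
  sig3 <- assemble_stemness(lists, curated = fx$planted[2])
  expect_setequal(sig3$genes, fx$planted)
})

test_that("ortholog mapping drops and warns on unmapped genes", {
  map <- data.frame(source_id = c("A", "B"), target_id = c("a", "b"))
  expect_warning(
    sig <- assemble_stemness(list(c("A", "B", "C")), ortholog_map = map),
    "missing from the ortholog map")
  expect_setequal(sig$genes, c("a", "b"))
})

test_that("overlap matrix equals brute-force intersection counts", {
  set.seed(31)
  sets <- list(x = sample(letters, 10), y = sample(letters, 15),
               z = sample(LETTERS, 5))
  om <- overlap_matrix(sets)
  expect_equal(om$counts["x", "x"], 10L)
  expect_equal(om$counts["x", "z"], 0L)
  expect_equal(om$counts["x", "y"],
               length(intersect(sets$x, sets$y)))
  expect_equal(om$counts, t(om$counts))
  expect_equal(om$fractions["x", "y"], om$counts["x", "y"] / 10)
  expect_equal(om$fractions["y", "x"], om$counts["x", "y"] / 10)
})

test_that("matched control set reproduces the signature's expression-bin
           histogram deterministically", {
  set.seed(41)
  v <- matrix(rnorm(400 * 4, rep(seq(2, 10, length.out = 400), 4)), 400, 4,
              dimnames = list(sprintf("g%03d", 1:400), paste0("s", 1:4)))
  m <- toy_log_matrix(v, rep("tumor", 4))
  sig <- gene_signature("sig", sample(rownames(v), 60))
  ctl <- matched_control_set(m, sig, n_bins = 8, seed = 9)
  expect_length(intersect(ctl$genes, sig$genes), 0)
  expect_length(ctl$genes, 60)
  ctl2 <- matched_control_set(m, sig, n_bins = 8, seed = 9)
  expect_identical(ctl$genes, ctl2$genes)
  # bin histograms match exactly, so the mean-expression distributions
  # agree below the binning resolution
  mu <- rowMeans(v)
  breaks <- seq(min(mu), max(mu), length.out = 9)
  expect_equal(tabulate(cut(mu[ctl$genes], breaks, include.lowest = TRUE,
                            labels = FALSE), 8),
               tabulate(cut(mu[sig$genes], breaks, include.lowest = TRUE,
                            labels = FALSE), 8))
  ks <- suppressWarnings(
    ks.test(mu[ctl$genes], mu[sig$genes])$statistic)
  expect_lt(unname(ks), 0.25) # below one bin's mass resolution
  # a starved bin is reported by number
  tiny <- gene_signature("tiny", rownames(v)[mu <= sort(mu)[3]])
  expect_error(matched_control_set(m, tiny, n_bins = 200, seed = 1), "bin")
})

test_that("gene list files round-trip through the reader", {
  d <- withr::local_tempdir()
  f1 <- file.path(d, "plain.txt")
  writeLines(c("A", "B", "C"), f1)
  s1 <- read_gene_signature(f1, "plain")
  expect_setequal(s1$genes, c("A", "B", "C"))
  f2 <- file.path(d, "tagged.tsv")
  writeLines(c("A\tcurated", "B\tatlas"), f2)
  s2 <- read_gene_signature(f2, "tagged")
  expect_equal(unname(s2$tags[c("A", "B")]), c("curated", "atlas"))
})

test_that("bundled signature lists carry the published cardinalities", {
  p <- read_gene_signature(
    system.file("extdata", "proliferation_signature_synthetic.txt",
                package = "stemsig"), "proliferation", "proliferation")
  e <- read_gene_signature(
    system.file("extdata", "emt_met_signature_synthetic.txt",
                package = "stemsig"), "emt_met", "emt_met")
  expect_length(p, 326)
  expect_length(e, 51)
  expect_true(all(c("SNAI1", "SNAI2", "GRHL1", "GRHL2", "GRHL3") %in%
                    e$genes))
})
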