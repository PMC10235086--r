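test_that("coverage profiles conserve mass and add linearly", {
  model <- toyModel()   # core 1001-1117, window 500
  sheet <- oneSampleSheet()
  ## one fragment covering exactly the core: 117 positions, each once
  cf <- classifyFragments(frag(1001, 1117), model)
  p <- coverageProfile(cf, model, sheet)
  v <- profileValues(p)
  expect_equal(sum(v$value), 117)
  expect_equal(v$value[v$offset %in% 0:116 & v$strand == "+"],
               rep(1, 117))
  expect_equal(sum(v$value[v$strand == "-"]), 0)
  ## two identical fragments double the profile exactly
  cf2 <- classifyFragments(c(frag(1001, 1117), frag(1001, 1117)), model)
  v2 <- profileValues(coverageProfile(cf2, model, sheet))
  expect_equal(v2$value, 2 * v$value)
  ## mass equals summed overlap with the profiled region, clipping included
  cf3 <- classifyFragments(frag(c(400, 901), c(1050, 2000)), model)
  v3 <- profileValues(coverageProfile(cf3, model, sheet))
  expect_equal(sum(v3$value), (1050 - 501 + 1) + (1617 - 901 + 1))
})

test_that("per-chromosome contributions superpose in CEN-anchored space", {
  cores <- GenomicRanges::GRanges(c("c1", "c2"),
    IRanges::IRanges(c(2001L, 7001L), width = 117L))
  model <- CenGenomeModel(c(c1 = 20000L, c2 = 20000L), cores,
                          coreWidthBand = NULL)
  sheet <- oneSampleSheet()
  ## same CEN-relative offsets (-100..49) on both chromosomes
  both <- GenomicRanges::GRanges(c("c1", "c2"),
    IRanges::IRanges(c(1901, 6901), c(2050, 7050)), strand = "+")
  both$sample <- c("s1", "s1")
  f1 <- both[1]
  f2 <- both[2]
  both <- classifyFragments(both, model)
  vBoth <- profileValues(coverageProfile(both, model, sheet))
  v1 <- profileValues(coverageProfile(classifyFragments(f1, model),
                                      model, sheet))
  v2 <- profileValues(coverageProfile(classifyFragments(f2, model),
                                      model, sheet))
  expect_equal(vBoth$value, v1$value + v2$value)
  expect_equal(vBoth$value[vBoth$offset %in% (-100:49) &
                             vBoth$strand == "+"], rep(2, 150))
})

test_that("start sites are strand-aware 5' ends and conserve counts", {
  model <- toyModel()
  sheet <- oneSampleSheet()
  ## minus-strand span 901-1050: the 5' end is the rightmost base 1050
  cf <- classifyFragments(frag(901, 1050, "-"), model)
  v <- profileValues(startSiteProfile(cf, model, sheet))
  expect_equal(sum(v$value), 1)
  expect_equal(v$value[v$offset == 1050 - 1001 & v$strand == "-"], 1)
  ## two fragments sharing a start stack at one position
  cf2 <- classifyFragments(frag(c(950, 950, 960), c(1100, 1150, 1160)),
                           model)
  v2 <- profileValues(startSiteProfile(cf2, model, sheet))
  expect_equal(sum(v2$value), 3)
  expect_equal(max(v2$value), 2)
  ## a long fragment whose 5' end lies outside the profiled region
  ## contributes nothing, so mass equals the in-window 5'-end count
  cf3 <- classifyFragments(frag(300, 1050), model)
  expect_equal(sum(profileValues(
    startSiteProfile(cf3, model, sheet))$value), 0)
})

test_that("CPM normalisation scales by library depth before aggregation", {
  model <- toyModel()
  ## unit denominator: CPM equals RAW
  sheet1 <- oneSampleSheet(total = 1e6)
  cf <- classifyFragments(frag(1001, 1117), model)
  raw <- coverageProfile(cf, model, sheet1)
  cpm <- cpmNormalise(raw, sheet1)
  expect_equal(sum(profileValues(cpm)$value), 117)
  ## doubled depth halves the CPM
  sheet2 <- oneSampleSheet(total = 2e6)
  expect_equal(sum(profileValues(cpmNormalise(raw, sheet2))$value),
               117 / 2)
  ## mixed-depth condition: hand-computed weighted sum on 3 fragments
  ## s1 (depth 1e6): spans 1001-1010 and 1001-1005; s2 (depth 2e6):
  ## span 1001-1010. At offsets 0..4 cpm = 2*1 + 0.5*1; at 5..9 = 1 + 0.5
  sheet <- sampleSheet(c("s1", "s2"), c("mock", "mock"), 1:2, c(1e6, 2e6))
  f <- c(frag(c(1001, 1001), c(1010, 1005), sample = "s1"),
         frag(1001, 1010, sample = "s2"))
  p <- cpmNormalise(coverageProfile(classifyFragments(f, model), model,
                                    sheet), sheet)
  v <- profileValues(p)
  expect_equal(v$value[v$offset %in% 0:4 & v$strand == "+"], rep(2.5, 5))
  expect_equal(v$value[v$offset %in% 5:9 & v$strand == "+"], rep(1.5, 5))
  ## mean mode averages replicates instead of summing
  pm <- cpmNormalise(coverageProfile(classifyFragments(f, model), model,
                                     sheet), sheet, aggregate = "mean")
  vm <- profileValues(pm)
  expect_equal(vm$value[vm$offset %in% 0:4 & vm$strand == "+"],
               rep(1.25, 5))
  ## error taxonomy
  expect_error(cpmNormalise(p, sheet), "already")
  zero <- sampleSheet("s1", "mock", 1L, 0)
  rawZ <- coverageProfile(classifyFragments(frag(1001, 1010), model),
                          model, zero)
  expect_error(cpmNormalise(rawZ, zero), "zero")
})

test_that("profile geometry must match the classification geometry", {
  model <- toyModel()
  cf <- classifyFragments(frag(1001, 1117), model)
  expect_error(coverageProfile(cf, model, oneSampleSheet(),
                               windowBp = 200L), "geometry")
  expect_error(startSiteProfile(cf, model, oneSampleSheet(),
                                windowBp = 200L), "geometry")
})

test_that("start-site counting reports distinct positions and totals", {
  region <- GenomicRanges::GRanges("chrT", IRanges::IRanges(500, 1617))
  f <- frag(c(950, 950, 960), c(1100, 1150, 1160))
  expect_equal(startSiteCount(f, region), list(distinct = 2L, total = 3L))
  empty <- GenomicRanges::GRanges("chrT", IRanges::IRanges(5000, 5100))
  expect_equal(startSiteCount(f, empty), list(distinct = 0L, total = 0L))
  expect_equal(startSiteCount(f[0], region),
               list(distinct = 0L, total = 0L))
})

test_that("depletion multiplies distinct centromeric start sites", {
  ## Monte-Carlo property: with the packaged depletion multipliers the
  ## auxin cohort shows more distinct CEN start positions than mock in
  ## at least 95% of seeded runs
  cfg <- simulationConfig(cenTotal = 200, scale = 1, noncodingTotal = 0,
                          backgroundFragments = 0, replicates = 1)
  model <- simulateGenome(cfg)
  region <- GenomicRanges::resize(cenCores(model),
    BiocGenerics::width(cenCores(model)) + 2L * periWindowBp(model),
    fix = "center")
  wins <- vapply(1:100, function(s) {
    mo <- simulateFragments(model, cfg, "mock", 1, seed = s)$fragments
    au <- simulateFragments(model, cfg, "auxin", 1, seed = s)$fragments
    startSiteCount(au, region)$distinct >
      startSiteCount(mo, region)$distinct
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})
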