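test_that("simulated genomes honour the configured geometry", {
  cfg <- simulationConfig(seed = 4L)
  model <- simulateGenome(cfg)
  cores <- cenCores(model)
  expect_equal(length(cores), 16L)
  expect_true(all(BiocGenerics::width(cores) %in% 115:119))
  expect_equal(length(periOrfs(model)), 22L)
  ## no ORF within the 200 bp clearance of any core
  gaps <- GenomicRanges::distance(
    periOrfs(model),
    cores[match(as.character(GenomeInfoDb::seqnames(periOrfs(model))),
                as.character(GenomeInfoDb::seqnames(cores)))])
  expect_true(all(gaps >= 200L))   # the inner 200 bp stay ORF-free
  ## deterministic: same seed, identical annotation bytes
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  writeGenomeModel(model, d1)
  writeGenomeModel(simulateGenome(cfg), d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("condition class counts implement the depletion multipliers", {
  cfg <- simulationConfig(scale = 1)
  mo <- conditionClassCounts(cfg, "mock")
  au <- conditionClassCounts(cfg, "auxin")
  expect_equal(unname(mo), c(21, 21, 16369, 163690))
  ## net CEN fold 2.3 borne by the short class; long unchanged
  expect_equal(unname(au[["longCen"]]), 21)
  expect_equal((au[["shortCen"]] + au[["longCen"]]) /
                 (mo[["shortCen"]] + mo[["longCen"]]), 2.3)
  expect_equal(au[["noncoding"]] / mo[["noncoding"]], 1.9)
  expect_equal(au[["coding"]], mo[["coding"]])
})

test_that("every simulated fragment realises its intended class", {
  cfg <- simulationConfig(cenTotal = 600, scale = 1, noncodingTotal = 600,
                          codingMultiplier = 1, backgroundFragments = 400,
                          replicates = 1)
  model <- simulateGenome(cfg)
  r <- simulateFragments(model, cfg, "mock", 1)
  cl <- classifyFragments(r$fragments, model)
  counts <- table(cl$tclass)
  ## Poisson draws around the configured expectations
  expect_gt(counts[["CEN"]], 500); expect_lt(counts[["CEN"]], 700)
  expect_gt(counts[["PERICEN_NONCODING"]], 500)
  expect_gt(counts[["PERICEN_CODING"]], 500)
  expect_gt(counts[["OTHER"]], 300)
  expect_equal(r$sheetRow$totalFragments, length(r$fragments))
  ## no centromeric class at all when the cen total is zero
  cfg0 <- simulationConfig(cenTotal = 0, scale = 1, noncodingTotal = 200,
                           codingMultiplier = 0, backgroundFragments = 0,
                           replicates = 1)
  r0 <- simulateFragments(model, cfg0, "mock", 1)
  expect_false(any(classifyFragments(r0$fragments, model)$tclass ==
                     "CEN"))
})

test_that("the generator recovers its configured composition and bias", {
  cfg <- simulationConfig(cenTotal = 5000, scale = 1, noncodingTotal = 0,
                          backgroundFragments = 0, replicates = 1)
  model <- simulateGenome(cfg)
  cl <- classifyFragments(
    simulateFragments(model, cfg, "mock", 1)$fragments, model)
  cen <- cl[cl$tclass == "CEN"]
  n <- length(cen)
  ## termination composition within 4 binomial sd of the packaged values
  comp <- cfg$termCompMock
  for (cls in names(comp)) {
    phat <- mean(cen$termClass == cls)
    tol <- 4 * sqrt(comp[[cls]] * (1 - comp[[cls]]) / n)
    expect_lt(abs(phat - comp[[cls]]), tol)
  }
  ## pericentromeric initiation probability
  expect_lt(abs(mean(cen$initiatedInPericen) - 0.79),
            4 * sqrt(0.79 * 0.21 / n))
  ## plus-strand dominance on the configured majority of chromosomes
  byChrom <- tapply(as.character(BiocGenerics::strand(cen)) == "+",
                    as.character(GenomeInfoDb::seqnames(cen)), mean)
  expect_gte(sum(byChrom > 0.5), 10L)
})

test_that("depletion shifts the short:long ratio towards three", {
  cfg <- simulationConfig(cenTotal = 3000, scale = 1, noncodingTotal = 0,
                          backgroundFragments = 0, replicates = 1)
  model <- simulateGenome(cfg)
  au <- classifyFragments(
    simulateFragments(model, cfg, "auxin", 1)$fragments, model)
  cenA <- au[au$tclass == "CEN"]
  ratio <- sum(cenA$lengthClass == "SHORT") /
    sum(cenA$lengthClass == "LONG")
  expect_gt(ratio, 2.8); expect_lt(ratio, 4.5)
  mo <- classifyFragments(
    simulateFragments(model, cfg, "mock", 1)$fragments, model)
  cenM <- mo[mo$tclass == "CEN"]
  ratioM <- sum(cenM$lengthClass == "SHORT") /
    sum(cenM$lengthClass == "LONG")
  expect_gt(ratioM, 0.85); expect_lt(ratioM, 1.18)
})

test_that("replicate streams differ but runs reproduce byte for byte", {
  cfg <- simulationConfig(cenTotal = 300, scale = 1, noncodingTotal = 300,
                          codingMultiplier = 1, backgroundFragments = 100,
                          replicates = 2)
  model <- simulateGenome(cfg)
  r1a <- simulateFragments(model, cfg, "mock", 1)
  r1b <- simulateFragments(model, cfg, "mock", 1)
  r2 <- simulateFragments(model, cfg, "mock", 2)
  expect_identical(r1a$fragments, r1b$fragments)
  expect_false(identical(IRanges::ranges(r1a$fragments),
                         IRanges::ranges(r2$fragments)))
})

test_that("a full simulated experiment is consistent and writable", {
  cfg <- simulationConfig(cenTotal = 200, scale = 1, noncodingTotal = 400,
                          codingMultiplier = 1, backgroundFragments = 200,
                          replicates = 2)
  dir <- file.path(withr::local_tempdir(), "expt")
  sim <- simulateExperiment(cfg, dir = dir)
  expect_equal(nrow(sim$sheet), 4L)
  expect_equal(sort(unique(sim$sheet$condition)), c("auxin", "mock"))
  expect_equal(names(sim$fragments), sim$sheet$sample)
  expect_true(all(file.exists(unlist(sim$paths))))
  ## written fragments reload to the in-memory records
  s <- sim$sheet$sample[1]
  reread <- readFragmentsBed(sim$paths[[s]], s)
  expect_equal(IRanges::ranges(reread),
               IRanges::ranges(sim$fragments[[s]]))
  ## reference genes carry the published copy numbers and positive counts
  expect_equal(sim$refGenes$copiesPerCell, c(2.6, 5.0, 3.1, 13.4))
  expect_true(all(sim$refGenes$count > 0))
  ## refuses to clobber without the flag
  expect_error(simulateExperiment(cfg, dir = dir), "overwrite")
  expect_silent(sim2 <- simulateExperiment(cfg, dir = dir,
                                           overwrite = TRUE))
})

test_that("infeasible configurations fail fast at validation", {
  expect_error(simulationConfig(pericenInitP = 1.2), "\\[0, 1\\]")
  expect_error(simulationConfig(termCompMock = c(FULL_CEN = 1, CDEI = 0,
                                                 CDEII = 0, CDEIII = -1)),
               "composition")
  expect_error(simulationConfig(shortCenMedian = 1500), "threshold")
  expect_error(simulationConfig(coreWidthBand = c(30L, 35L)), "CDEII")
  expect_error(simulationConfig(chromosomeLength = 1000L), "short")
  expect_error(simulationConfig(auxinCenFold = 0.3,
                                auxinLongCenFold = 1.0), "negative")
})
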