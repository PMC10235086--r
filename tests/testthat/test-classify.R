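test_that("classification matches the worked boundary cases", {
  model <- toyModel()   # core 1001-1117, CDEs 1001-1008/1009-1092/1093-1117
  f <- frag(c(901, 991, 601, 101), c(1050, 1200, 840, 300), "+")
  cf <- classifyFragments(f, model)
  expect_equal(cf$tclass, c("CEN", "CEN", "PERICEN_NONCODING", "OTHER"))
  ## end boundary 1050 sits in CDEII; start is upstream of the core
  expect_equal(cf$termClass[1], "CDEII")
  expect_true(cf$initiatedInPericen[1])
  expect_equal(cf$lengthClass[1], "SHORT")
  ## covers the whole core
  expect_equal(cf$termClass[2], "FULL_CEN")
  expect_equal(cf$side[3], "UP")
  expect_equal(cf$side[4], "NONE")
  ## the derived cases agree with the independent position-set oracle
  g <- oracleGeom(model)
  orc <- oracleClassify(BiocGenerics::start(f), BiocGenerics::end(f),
                        as.character(BiocGenerics::strand(f)), g)
  expect_equal(cf$tclass, orc$tclass)
  expect_equal(cf$termClass, orc$termClass)
  expect_equal(cf$initiatedInPericen, orc$initiatedInPericen)
  expect_equal(cf$side, orc$side)
})

test_that("length classes split at the documented boundary", {
  expect_equal(lengthClass(231), "SHORT")   # the short-class median
  expect_equal(lengthClass(4458), "LONG")   # the long-class median
  expect_equal(lengthClass(999), "SHORT")
  expect_equal(lengthClass(1000), "LONG")   # boundary value is LONG
  expect_equal(lengthClass(c(125, 9376)), c("SHORT", "LONG"))
})

test_that("classification errors on fragments from unknown chromosomes", {
  model <- toyModel()
  expect_error(classifyFragments(frag(10, 20, chrom = "chrQ"), model),
               "chrQ")
})

test_that("pericentromeric set equals window hits minus core hits", {
  ## exhaustive subtraction equivalence on a compact toy chromosome
  model <- toyModel(chromLen = 300L, coreStart = 141L, coreWidth = 20L,
                    windowBp = 40L, cde1Len = 4L, cde3Len = 6L)
  s <- rep(1:300, each = 30)
  e <- s + rep(seq(0, 290, by = 10), times = 300)
  keep <- e <= 300
  f <- frag(s[keep], e[keep])
  cf <- classifyFragments(f, model)
  core <- cenCores(model)
  win <- periWindows(model)
  winHit <- IRanges::overlapsAny(f, win, ignore.strand = TRUE)
  coreHit <- IRanges::overlapsAny(f, core, ignore.strand = TRUE)
  expect_equal(cf$tclass %in% c("PERICEN_NONCODING", "PERICEN_CODING"),
               winHit & !coreHit)
  expect_equal(cf$tclass == "CEN", coreHit)
})

test_that("classification is mirror-symmetric through the chromosome", {
  L <- 10000L
  model <- toyModel(chromLen = L, coreStart = 4001L, coreWidth = 117L)
  ## reflected model: element sizes swap so the left-most element is the
  ## reflection of CDEIII
  mirror <- toyModel(chromLen = L, coreStart = L + 1L - 4117L,
                     coreWidth = 117L, cde1Len = 25L, cde3Len = 8L)
  set.seed(21)
  s <- sample(3400:4700, 200, replace = TRUE)
  e <- s + sample(10:900, 200, replace = TRUE)
  st <- sample(c("+", "-"), 200, replace = TRUE)
  cf <- classifyFragments(frag(s, e, st), model)
  cfm <- classifyFragments(
    frag(L + 1L - e, L + 1L - s, ifelse(st == "+", "-", "+")), mirror)
  expect_equal(cfm$tclass, cf$tclass)
  mapTerm <- c(FULL_CEN = "FULL_CEN", CDEI = "CDEIII", CDEII = "CDEII",
               CDEIII = "CDEI", NONE = "NONE")
  expect_equal(cfm$termClass, unname(mapTerm[cf$termClass]))
  mapSide <- c(UP = "DOWN", DOWN = "UP", BOTH = "BOTH", NONE = "NONE")
  expect_equal(cfm$side, unname(mapSide[cf$side]))
  expect_equal(cfm$initiatedInPericen, cf$initiatedInPericen)
})

test_that("no coding calls arise within the ORF clearance zone", {
  ## ORFs only >200 bp from the core: fragments confined to the inner
  ## 200 bp of the windows can never be PERICEN_CODING
  orf <- GenomicRanges::GRanges("chrT", IRanges::IRanges(550, 790),
                                strand = "+")
  orf$id <- "ORF1"
  model <- toyModel(orfs = orf)  # core 1001-1117; ORF ends 210 bp upstream
  s <- 801:1000
  f <- frag(s, pmin(s + 150L, 1000L))
  cf <- classifyFragments(f, model)
  expect_false(any(cf$tclass == "PERICEN_CODING"))
  ## but a fragment reaching the ORF is coding
  cf2 <- classifyFragments(frag(700, 900), model)
  expect_equal(cf2$tclass, "PERICEN_CODING")
  ## strand-matched mode ignores opposite-strand ORFs
  cf3 <- classifyFragments(frag(700, 900, "-"), model,
                           codingStrandMatched = TRUE)
  expect_equal(cf3$tclass, "PERICEN_NONCODING")
})

test_that("tallies count exactly, ignore order, and validate samples", {
  model <- toyModel()
  f <- c(frag(c(990, 995, 1000), c(1200, 1210, 1220)),      # 3 CEN
         frag(c(601, 640), c(840, 860)))                    # 2 noncoding
  sheet <- oneSampleSheet()
  tal <- tallyFragments(classifyFragments(f, model), sheet)
  expect_equal(sum(tal$count), 5L)
  byClass <- tapply(tal$count, tal$tclass, sum)
  expect_equal(unname(byClass[["CEN"]]), 3L)
  expect_equal(unname(byClass[["PERICEN_NONCODING"]]), 2L)
  set.seed(5)
  tal2 <- tallyFragments(classifyFragments(f[sample(5)], model), sheet)
  expect_equal(tal2, tal)
  empty <- classifyFragments(frag(1, 2)[0], model)
  expect_equal(sum(tallyFragments(empty, sheet)$count), 0L)
  bad <- classifyFragments(f, model)
  bad$sample <- "ghost"
  expect_error(tallyFragments(bad, sheet), "ghost")
})

test_that("termination-class fractions are normalised and strand-split", {
  model <- toyModel()
  f <- c(frag(c(990, 992), c(1200, 1210), "+"),  # 2 FULL_CEN plus
         frag(991, 1205, "-"),                   # 1 FULL_CEN minus
         frag(901, 1050, "+"))                   # 1 CDEII
  tal <- tallyFragments(classifyFragments(f, model), oneSampleSheet())
  d <- termClassDistribution(tal, "mock")
  expect_equal(sum(d$fraction), 1)
  expect_equal(d$fraction[d$termClass == "FULL_CEN" & d$strand == "+"],
               0.5)
  expect_equal(d$fraction[d$termClass == "FULL_CEN" & d$strand == "-"],
               0.25)
  expect_equal(sum(d$fraction[d$termClass == "CDEII"]), 0.25)
  ## all-FULL input concentrates the distribution
  f2 <- frag(c(990, 992), c(1200, 1210), "+")
  tal2 <- tallyFragments(classifyFragments(f2, model), oneSampleSheet())
  d2 <- termClassDistribution(tal2, "mock")
  expect_equal(sum(d2$fraction[d2$termClass == "FULL_CEN"]), 1)
  expect_error(termClassDistribution(tal2, "auxin"), "no CEN")
})

test_that("classified fragments never hold inconsistent annotations", {
  ## term/length classes only for CEN; CEN fragments have a side unless
  ## wholly inside the core
  model <- toyModel()
  set.seed(9)
  s <- sample(400:1700, 400, replace = TRUE)
  f <- frag(s, s + sample(5:800, 400, replace = TRUE),
            sample(c("+", "-"), 400, replace = TRUE))
  cf <- classifyFragments(f, model)
  isCen <- cf$tclass == "CEN"
  expect_true(all((cf$termClass != "NONE") == isCen))
  expect_true(all((cf$lengthClass != "NONE") == isCen))
  core <- cenCores(model)
  inside <- BiocGenerics::start(cf) >= BiocGenerics::start(core) &
    BiocGenerics::end(cf) <= BiocGenerics::end(core)
  expect_true(all(cf$side[isCen & !inside] != "NONE"))
})
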