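test_that("atomic alpha and epsilon follow the core-count formulas", {
  expect_equal(atomicAlpha("H"), 0)
  expect_equal(atomicAlpha("C"), 0.5)            # (6-4)/4 / (2-1)
  expect_equal(atomicAlpha("Cl"), 10 / 7 / 2, tolerance = 1e-12)
  expect_equal(atomicEpsilon("H"), 0.3)
  expect_equal(atomicEpsilon("C"), 0.7)          # -0.5 + 1.2
  expect_equal(atomicEpsilon("O"), -1 / 3 + 1.8, tolerance = 1e-12)
})

test_that("sigma contributions split at the similarity threshold", {
  expect_equal(sigmaContribution("C", "C"), 0.5)
  expect_equal(sigmaContribution("C", "O"), 0.75)
  expect_equal(sigmaContribution("N", "O"), 0.75)  # |1.1 - 1.4667| > 0.3
  expect_equal(sigmaContribution("C", "S"), 0.5)   # |0.7 - 0.9| <= 0.3
})

test_that("VEM beta components bookkeep sigma, pi, aromatic and lone pairs", {
  propane <- parseOne("CCC", "propane")
  central <- atomBeta(propane, 2)
  expect_equal(central$betaS, 1.0)
  expect_equal(central$betaNs, 0)

  acetone <- parseOne("CC(=O)C", "acetone")
  oIdx <- which(atomTable(heavySkeleton(acetone))$element == "O")
  expect_equal(atomBeta(acetone, oIdx)$betaNs, 1.5)  # dissimilar pi bond

  benz <- parseOne("c1ccccc1", "benzene")
  for (i in 1:6) expect_equal(atomBeta(benz, i)$betaNs, 2.0)

  phenol <- parseOne("Oc1ccccc1", "phenol")
  oIdx <- which(atomTable(heavySkeleton(phenol))$element == "O")
  expect_equal(atomBeta(phenol, oIdx)$betaNs, 0.5)  # lone-pair conjugation
})

test_that("reference alkane replaces heteroatoms and saturates all bonds", {
  res <- fixtureMols()[["49"]]
  ra <- referenceAlkane(res)
  expect_true(all(atomTable(ra)$element %in% c("C", "H")))
  expect_true(all(bondTable(ra)$order == 1L))
  expect_equal(nAtoms(ra), 24)  # 8 heavy + 16 H

  hexane <- parseOne("CCCCCC", "hexane")
  expect_equal(formulaOf(referenceAlkane(hexane)), formulaOf(hexane))

  benz <- parseOne("c1ccccc1", "benzene")
  cyclohexane <- parseOne("C1CCCCC1", "chx")
  expect_equal(formulaOf(referenceAlkane(benz)), formulaOf(cyclohexane))
})

test_that("saturated skeleton demotes only carbon-carbon multiple bonds", {
  lim <- fixtureMols()[["50"]]
  ss <- saturatedSkeleton(lim)
  pMenthane <- parseOne("CC(C)C1CCC(C)CC1", "pmenthane")
  expect_equal(formulaOf(ss), formulaOf(pMenthane))

  ethanol <- parseOne("CCO", "ethanol")
  expect_equal(formulaOf(saturatedSkeleton(ethanol)), formulaOf(ethanol))

  acetone <- parseOne("CC(=O)C", "acetone")  # C=O kept
  expect_equal(sum(bondTable(heavySkeleton(saturatedSkeleton(acetone)))$order == 2L), 1)

  camphene <- fixtureMols()[["1"]]
  expect_equal(formulaOf(saturatedSkeleton(camphene)),
               formulaOf(referenceAlkane(camphene)))
})

test_that("epsilon variants coincide where the derived graphs coincide", {
  hexane <- parseOne("CCCCCC", "hexane")
  ev <- epsilonVariants(hexane)
  expect_equal(ev[["eps3"]], ev[["eps2"]])
  expect_equal(ev[["eps4"]], ev[["eps2"]])
  expect_equal(ev[["eps5"]], ev[["eps2"]])

  cam <- epsilonVariants(fixtureMols()[["1"]])
  expect_equal(cam[["eps3"]], cam[["eps4"]])

  res <- epsilonVariants(fixtureMols()[["49"]])
  expect_gt(res[["eps5"]], res[["eps2"]])
})

test_that("composite descriptors satisfy the sign and ordering properties", {
  desc <- etaDescriptors(fixtureMols())
  hetero <- setdiff(rownames(desc), HYDROCARBON_IDS)

  expect_true(all(desc[, "ETA_dEpsilon_C"] <= 1e-12))
  expect_true(all(abs(desc[HYDROCARBON_IDS, "ETA_dEpsilon_C"]) < 1e-12))
  expect_true(all(desc[hetero, "ETA_dEpsilon_C"] < 0))

  expect_true(all(desc[, "ETA_dEpsilon_D"] >= -1e-12))
  expect_true(all(abs(desc[HYDROCARBON_IDS, "ETA_dEpsilon_D"]) < 1e-12))
  expect_gt(desc["49", "ETA_dEpsilon_D"], 0)

  expect_true(all(desc[, "ETA_dAlpha_B"] >= 0))
  expect_equal(desc["50", "ETA_dAlpha_B"], 0)

  expect_true(all(desc[, "ETA_EtaP_F"] >= 0))
  expect_gt(desc["10", "ETA_EtaP_F"], desc["4", "ETA_EtaP_F"])

  expect_lt(desc["50", "ETA_BetaP_s"], desc["44", "ETA_BetaP_s"])
  expect_equal(desc[, "ETA_BetaP_s"], desc[, "ETA_Beta_s"] / desc[, "Nv"])
  expect_equal(desc[, "ETA_dEpsilon_C"],
               desc[, "ETA_Epsilon_3"] - desc[, "ETA_Epsilon_4"])
  expect_true(all(is.finite(desc)))
})

test_that("descriptors are invariant to the atom order of the input", {
  variants <- c("CC(=C)C1CCC(C)=CC1",    # isopropenyl-first
                "C1=C(C)CCC(C1)C(=C)C",  # ring-first
                "CC1=CCC(CC1)C(C)=C")    # methyl-first
  vals <- lapply(seq_along(variants),
                 function(i) etaComposite(parseOne(variants[i], paste0("v", i))))
  expect_equal(vals[[1]], vals[[2]], tolerance = 1e-12)
  expect_equal(vals[[1]], vals[[3]], tolerance = 1e-12)
})

test_that("single-heavy-atom and disconnected inputs are handled", {
  methane <- parseOne("C", "methane")
  d <- etaComposite(methane)
  expect_equal(d[["ETA_Eta"]], 0)
  expect_equal(d[["ETA_Eta_F"]], 0)
  salt <- moleculeFromGraph("pair", c("C", "C"),
                            data.frame(from = integer(), to = integer(),
                                       order = integer()))
  expect_error(etaComposite(salt), "disconnected")
})
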