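test_that("exchange reactions are auto-detected by the single-metabolite rule", {
  m <- toy_chain_model()
  cls <- classify_reactions(m)
  expect_equal(cls$exchange, "EX_a")
  expect_setequal(cls$biological, c("T_ab", "BM"))
  expect_equal(m$rxn_ids[m$biomass], "BM")
  # partition property
  expect_setequal(c(cls$exchange, cls$biological), m$rxn_ids)
  expect_length(intersect(cls$exchange, cls$biological), 0)
})

test_that("duplicate ids and malformed inputs are rejected", {
  rx <- data.frame(id = c("R1", "R1"), formula = c("a ->", "a -> b"),
                   lb = 0, ub = 1)
  expect_error(stoich_model(rx, biomass = "R1"), "duplicate reaction")
  rx2 <- data.frame(id = "R1", formula = "a -> b", lb = 2, ub = 1)
  expect_error(stoich_model(rx2, biomass = "R1"), "lb > ub")
  rx3 <- data.frame(id = "R1", formula = "a -> b -> c", lb = 0, ub = 1)
  expect_error(stoich_model(rx3, biomass = "R1"), "arrow")
})

test_that("classification matches a column-count oracle on random models", {
  set.seed(7)
  for (i in 1:10) {
    m <- random_tab_model(n_rxn = 12)
    oracle_exchange <- m$rxn_ids[colSums(m$S != 0) == 1L &
                                   seq_along(m$rxn_ids) != m$biomass]
    expect_setequal(classify_reactions(m)$exchange, oracle_exchange)
  }
})

test_that("tabular write/load round trip preserves the model exactly", {
  set.seed(21)
  for (i in 1:5) {
    m <- random_tab_model(n_rxn = 20)
    dir <- withr::local_tempdir()
    write_model_tabular(m, dir)
    m2 <- load_model(dir, "tabular")
    expect_equal(m2$S, m$S)
    expect_equal(m2$lb0, m$lb0)
    expect_equal(m2$ub0, m$ub0)
    expect_identical(m2$gpr, m$gpr)
    expect_equal(m2$rxn_ids[m2$biomass], m$rxn_ids[m$biomass])
    # a second round trip is byte-identical on disk
    dir2 <- withr::local_tempdir()
    write_model_tabular(m2, dir2)
    expect_identical(readLines(file.path(dir, "reactions.tsv")),
                     readLines(file.path(dir2, "reactions.tsv")))
  }
})

test_that("missing biomass configuration is a configuration error", {
  m <- toy_chain_model()
  dir <- withr::local_tempdir()
  write_model_tabular(m, dir)
  file.remove(file.path(dir, "biomass.txt"))
  expect_error(load_model(dir, "tabular"), "biomass")
  expect_s3_class(load_model(dir, "tabular", biomass = "BM"),
                  "stoich_model")
})

test_that("a minimal SBML L3/fbc file loads correctly", {
  sbml <- '<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"
      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"
      level="3" version="1">
 <model id="toy">
  <listOfParameters>
   <parameter id="lb_free" value="-10" constant="true"/>
   <parameter id="ub_free" value="10" constant="true"/>
   <parameter id="zero" value="0" constant="true"/>
  </listOfParameters>
  <listOfSpecies>
   <species id="a" name="metabolite a"/>
   <species id="b" name="metabolite b"/>
  </listOfSpecies>
  <fbc:listOfGeneProducts>
   <fbc:geneProduct fbc:id="G_x" fbc:label="gx"/>
   <fbc:geneProduct fbc:id="G_y" fbc:label="gy"/>
  </fbc:listOfGeneProducts>
  <listOfReactions>
   <reaction id="EX_a" reversible="true" fbc:lowerFluxBound="lb_free"
             fbc:upperFluxBound="ub_free">
    <listOfReactants>
     <speciesReference species="a" stoichiometry="1"/>
    </listOfReactants>
   </reaction>
   <reaction id="T1" reversible="false" fbc:lowerFluxBound="zero"
             fbc:upperFluxBound="ub_free">
    <listOfReactants>
     <speciesReference species="a" stoichiometry="1"/>
    </listOfReactants>
    <listOfProducts>
     <speciesReference species="b" stoichiometry="2"/>
    </listOfProducts>
    <fbc:geneProductAssociation>
     <fbc:or>
      <fbc:geneProductRef fbc:geneProduct="G_x"/>
      <fbc:geneProductRef fbc:geneProduct="G_y"/>
     </fbc:or>
    </fbc:geneProductAssociation>
   </reaction>
   <reaction id="BM" reversible="false" fbc:lowerFluxBound="zero"
             fbc:upperFluxBound="ub_free">
    <listOfReactants>
     <speciesReference species="b" stoichiometry="1"/>
    </listOfReactants>
   </reaction>
  </listOfReactions>
  <fbc:listOfObjectives fbc:activeObjective="obj">
   <fbc:objective fbc:id="obj" fbc:type="maximize">
    <fbc:listOfFluxObjectives>
     <fbc:fluxObjective fbc:reaction="BM" fbc:coefficient="1"/>
    </fbc:listOfFluxObjectives>
   </fbc:objective>
  </fbc:listOfObjectives>
 </model>
</sbml>'
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(sbml, path)
  m <- load_model(path, "sbml")
  expect_equal(sort(m$met_ids), c("a", "b"))
  expect_equal(m$rxn_ids[m$biomass], "BM")
  expect_equal(m$S["a", "T1"], -1)
  expect_equal(m$S["b", "T1"], 2)
  expect_equal(m$lb0[m$rxn_ids == "EX_a"], -10)
  expect_equal(m$gpr[["T1"]]$op, "or")
  expect_setequal(gpr_genes(m$gpr[["T1"]]), c("gx", "gy"))
  expect_equal(classify_reactions(m)$exchange, "EX_a")
})

test_that("validate_model reports structural problems and warnings", {
  m <- toy_chain_model()
  rep <- validate_model(m)
  expect_length(rep$errors, 0)

  bad <- m
  bad$lb0[2] <- 5  # above ub=10? make inconsistent:
  bad$lb0[2] <- 20
  rep2 <- validate_model(bad)
  expect_length(rep2$errors, 1)
  expect_match(rep2$errors, "lb > ub")

  # orphan genes in GPRs but not in expression data -> warning only
  rep3 <- validate_model(m, expression_genes = "other_gene")
  expect_length(rep3$errors, 0)
  expect_match(rep3$warnings, "g1", all = FALSE)

  # structurally blocked biomass -> warning
  blocked <- stoich_model(
    data.frame(id = c("EX_a", "T_ab", "BM"),
               formula = c("a ->", "a -> b", "b ->"),
               lb = c(0, 0, 0), ub = c(10, 10, 10)),
    biomass = "BM")
  rep4 <- validate_model(blocked)
  expect_match(rep4$warnings, "blocked", all = FALSE)
})
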