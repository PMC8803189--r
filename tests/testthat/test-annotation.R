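# Five toy nodes: AKT, JAGa, DLL4a, NRP1 and one bystander.
ec_nodes <- c("AKT", "JAGa", "DLL4a", "NRP1", "other")

test_that("stable marker signatures classify behaviors", {
  scheme <- ec_marker_scheme()
  phal <- make_attractor(list(c(1, 0, 0, 0, 0), c(1, 0, 1, 0, 1)))
  expect_identical(classify_behavior(phal, scheme, ec_nodes), "phalanx")
  tip <- make_attractor(list(c(0, 0, 1, 1, 0)))
  expect_identical(classify_behavior(tip, scheme, ec_nodes), "tip")
  stalk <- make_attractor(list(c(0, 1, 0, 0, 1)))
  expect_identical(classify_behavior(stalk, scheme, ec_nodes), "stalk")
})

test_that("oscillating or non-matching markers are atypical", {
  scheme <- ec_marker_scheme()
  # JAGa alternates 0/1 across the period-2 cycle
  osc <- make_attractor(list(c(1, 0, 0, 0, 0), c(1, 1, 0, 0, 0)))
  expect_identical(classify_behavior(osc, scheme, ec_nodes), "atypical")
  none <- make_attractor(list(c(0, 0, 0, 0, 0)))
  expect_identical(classify_behavior(none, scheme, ec_nodes), "atypical")
  expect_error(classify_behavior(osc, scheme, c("a", "b", "c", "d", "e")),
               "not in the network")
})

test_that("classification is invariant to cycle phase", {
  scheme <- ec_marker_scheme()
  a <- make_attractor(list(c(1, 0, 0, 0, 0), c(1, 0, 1, 0, 1)))
  b <- make_attractor(list(c(1, 0, 1, 0, 1), c(1, 0, 0, 0, 0)))
  expect_identical(classify_behavior(a, scheme, ec_nodes),
                   classify_behavior(b, scheme, ec_nodes))
})

test_that("overlapping user schemes raise a configuration error", {
  scheme <- marker_scheme(list(one = c(AKT = 1L), two = c(JAGa = 0L)))
  att <- make_attractor(list(c(1, 0, 0, 0, 0)))
  expect_error(classify_behavior(att, scheme, ec_nodes), "ambiguous")
})

# A 6-node bipartite-style fixture: two exclusive stage groups.
cc_nodes <- c("lic", "rep", "done", "sbp1", "sbp2", "aux")
cc_groups <- list(dna = c("lic", "rep", "done"), spb = c("sbp1", "sbp2"))

test_that("validity requires exactly one true member per group per state", {
  ok <- make_attractor(list(c(1, 0, 0, 1, 0, 0), c(0, 1, 0, 0, 1, 1),
                            c(0, 0, 1, 1, 0, 0)))
  v <- check_validity(ok, cc_groups, nodes = cc_nodes)
  expect_true(v$valid)
  expect_equal(nrow(v$violations), 0)

  two_true <- make_attractor(list(c(1, 1, 0, 1, 0, 0)))
  v2 <- check_validity(two_true, cc_groups, nodes = cc_nodes)
  expect_false(v2$valid)
  expect_identical(v2$violations$name, "dna")
  expect_equal(v2$violations$true_members, 2)
  expect_equal(v2$violations$state, 1)

  none_true <- make_attractor(list(c(1, 0, 0, 0, 0, 1)))
  v3 <- check_validity(none_true, cc_groups, nodes = cc_nodes)
  expect_false(v3$valid)
  expect_identical(v3$violations$name, "spb")
})

test_that("required components must stay represented in every state", {
  att <- make_attractor(list(c(1, 0, 0, 1, 0, 0), c(0, 1, 0, 0, 1, 0)))
  v <- check_validity(att, cc_groups,
                      required_components = list(aux = "aux"),
                      nodes = cc_nodes)
  expect_false(v$valid)
  expect_true(all(v$violations$what == "required_component"))
  expect_error(check_validity(att, list(g = c("lic", "nope")), nodes = cc_nodes),
               "unknown node")
})

test_that("viability requires a periodic attractor traversing every stage", {
  full <- make_attractor(list(c(1, 0, 0, 1, 0, 0), c(0, 1, 0, 0, 1, 1),
                              c(0, 0, 1, 1, 0, 0)))
  expect_identical(call_viability(full, cc_groups, cc_nodes), "viable")
  point <- make_attractor(list(c(1, 0, 0, 1, 0, 0)))
  expect_identical(call_viability(point, cc_groups, cc_nodes), "lethal")
  stuck <- make_attractor(list(c(1, 0, 0, 1, 0, 0), c(1, 0, 0, 0, 1, 1)))
  expect_identical(call_viability(stuck, cc_groups, cc_nodes), "lethal")
  invalid <- make_attractor(list(c(1, 1, 0, 1, 0, 0)))
  expect_error(call_viability(invalid, cc_groups, cc_nodes), "valid")
})

test_that("viable implies periodic and valid on random annotations", {
  set.seed(21)
  for (r in 1:50) {
    p <- sample(1:4, 1)
    att <- make_attractor(replicate(p, rbinom(6, 1, 0.5), simplify = FALSE))
    v <- check_validity(att, cc_groups, nodes = cc_nodes)
    verdict <- if (v$valid) call_viability(att, cc_groups, cc_nodes) else NA
    expect_true(!identical(verdict, "viable") || (v$valid && att$period > 1),
                label = paste("replicate", r))
  }
})

test_that("absent components are called against the reference attractor", {
  cmap <- list(geneA = c("lic", "rep"), geneB = c("sbp1", "sbp2"))
  ref <- make_attractor(list(c(1, 0, 0, 1, 0, 1), c(0, 1, 0, 0, 1, 1)))
  expect_identical(absent_components(ref, ref, cmap, cc_nodes)$absent,
                   character(0))
  # geneA forced constitutively 0, aux also silent but mapped to no component
  mut <- make_attractor(list(c(0, 0, 1, 1, 0, 0), c(0, 0, 1, 0, 1, 0)))
  ac <- absent_components(mut, ref, cmap, cc_nodes)
  expect_identical(ac$absent, "geneA")
  expect_identical(ac$residue, "aux")
  expect_error(absent_components(mut, ref, list(g = "zz"), cc_nodes),
               "unknown node")
})

test_that("census deduplicates by canonical identity and partitions counts", {
  a <- make_attractor(list(c(0, 1, 1, 0, 0, 0), c(1, 0, 0, 0, 0, 0)))
  b <- make_attractor(list(c(1, 0, 0, 0, 0, 0), c(0, 1, 1, 0, 0, 0)))  # same cycle
  c3 <- make_attractor(list(c(1, 1, 1, 1, 1, 1)))
  cen <- dedupe_and_census(list(a, b, a, c3))
  expect_length(cen$unique, 2)
  expect_equal(sum(cen$census$count), 2)
  expect_identical(sort(cen$census$period), c(1L, 2L))
  lab <- dedupe_and_census(list(a, b, c3), annotate = function(x)
    if (x$period > 1) "periodic" else "point")
  expect_identical(sort(lab$census$label), c("periodic", "point"))
})

test_that("the worked example's full census survives annotation counting", {
  atts <- enumerate_all_attractors(example_net())
  cen <- dedupe_and_census(atts)
  expect_equal(sum(cen$census$count[cen$census$period == 1]), 2)
  expect_equal(sum(cen$census$count[cen$census$period == 2]), 1)
})

test_that("annotation configs round-trip through their TSV formats", {
  tdir <- withr::local_tempdir()
  gf <- file.path(tdir, "groups.tsv")
  writeLines(c("group\tnode", "dna\tlic", "dna\trep", "dna\tdone",
               "spb\tsbp1", "spb\tsbp2"), gf)
  expect_identical(read_groups(gf), list(dna = c("lic", "rep", "done"),
                                         spb = c("sbp1", "sbp2")))
  mf <- file.path(tdir, "markers.tsv")
  writeLines(c("behavior\tnode\tvalue", "phalanx\tAKT\t1", "phalanx\tJAGa\t0",
               "phalanx\tNRP1\t0", "stalk\tJAGa\t1", "stalk\tNRP1\t0",
               "tip\tNRP1\t1", "tip\tDLL4a\t1", "tip\tAKT\t0"), mf)
  scheme <- read_markers(mf)
  expect_identical(scheme$behaviors$phalanx,
                   c(AKT = 1L, JAGa = 0L, NRP1 = 0L))
  cf <- file.path(tdir, "components.tsv")
  writeLines(c("component\tnode", "geneA\tlic", "geneA\trep"), cf)
  expect_identical(read_component_map(cf), list(geneA = c("lic", "rep")))
})
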