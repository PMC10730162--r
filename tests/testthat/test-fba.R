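test_that("model loading validates structure", {
  dir <- withr::local_tempdir()
  lc <- generate_toy_model("linear_chain")
  p <- file.path(dir, "lc.json")
  write_model_json(lc, p)
  m <- load_model(p, "json")
  expect_s3_class(m, "metabolic_model")
  expect_equal(m$biomass, "BIOMASS")
  expect_gte(length(m$exchanges), 1)
  expect_equal(lapply(m$reactions, `[[`, "stoich"),
               lapply(lc$reactions, `[[`, "stoich"))

  # lower bound above upper bound is rejected
  j <- jsonlite::read_json(p)
  j$reactions[[3]]$lb <- 5; j$reactions[[3]]$ub <- 1
  p2 <- file.path(dir, "bad.json")
  jsonlite::write_json(j, p2, auto_unbox = TRUE)
  expect_error(load_model(p2, "json"), "lower bound exceeds")

  # missing biomass
  j2 <- jsonlite::read_json(p); j2$biomass <- NULL
  p3 <- file.path(dir, "nob.json")
  jsonlite::write_json(j2, p3, auto_unbox = TRUE)
  expect_error(load_model(p3, "json"), "biomass")

  # dangling metabolite listed but unused
  j3 <- jsonlite::read_json(p)
  j3$metabolites <- c(j3$metabolites, "ghost")
  p4 <- file.path(dir, "dang.json")
  jsonlite::write_json(j3, p4, auto_unbox = TRUE)
  expect_error(load_model(p4, "json"), "ghost")
})

test_that("SBML subset round-trips stoichiometry", {
  dir <- withr::local_tempdir()
  for (nm in c("linear_chain", "branched")) {
    m <- generate_toy_model(nm)
    p <- file.path(dir, paste0(nm, ".xml"))
    write_model_sbml(m, p)
    back <- load_model(p, "sbml-subset")
    expect_setequal(names(back$reactions), names(m$reactions))
    for (rid in names(m$reactions)) {
      s1 <- m$reactions[[rid]]$stoich
      s2 <- back$reactions[[rid]]$stoich
      expect_equal(s2[sort(names(s2))], s1[sort(names(s1))], info = rid)
    }
    expect_setequal(back$metabolites, m$metabolites)
  }
})

test_that("apply_medium sets scenario bounds", {
  m <- generate_toy_model("linear_chain")
  cfg <- fva_config()
  anox <- apply_medium(m, cfg, "anoxic", source = "A")
  expect_equal(anox$reactions[[anox$exchanges[["o2"]]]]$lb, 0)
  expect_equal(anox$reactions[[anox$exchanges[["A"]]]]$lb, -100)
  aer <- apply_medium(m, cfg, "aerobic", source = "A")
  expect_equal(aer$reactions[[aer$exchanges[["o2"]]]]$lb, -10)
  micro <- apply_medium(m, cfg, "microaerobic", source = "A")
  expect_equal(micro$reactions[[micro$exchanges[["o2"]]]]$lb, -1)

  # glucose removed from the medium when requested
  cfg_g <- fva_config(medium = c(glc__D = 10, A = 5))
  with_glc <- apply_medium(m, fva_config(medium = c(A = 5),
                                         remove_glucose = FALSE), "anoxic")
  expect_equal(with_glc$reactions[[with_glc$exchanges[["A"]]]]$lb, -5)
  no_glc <- apply_medium(m, cfg_g, "anoxic")
  expect_false("glc__D" %in% names(no_glc$exchanges))

  expect_error(apply_medium(m, cfg, "anoxic", source = "unobtainium"),
               "not in model")
  expect_error(apply_medium(m, cfg, "hyperbaric"), "unknown oxygen")
})

test_that("growth maximization solves the hand LP", {
  m <- generate_toy_model("linear_chain")
  cfg <- fva_config()
  g <- max_growth(apply_medium(m, cfg, "anoxic", source = "A"))
  expect_equal(g$status, "optimal")
  expect_equal(g$mu, 100)      # 1:1 chain from 100 uptake

  # all exchanges closed: zero growth
  closed <- apply_medium(m, fva_config(), "anoxic", source = NULL)
  g0 <- max_growth(closed)
  expect_equal(g0$mu, 0)

  # forced flux through a blocked reaction is infeasible
  bt <- generate_toy_model("blocked_target")
  bt <- apply_medium(bt, cfg, "anoxic", source = "A")
  bt$reactions[["RT"]]$lb <- 1   # RT needs T, which nothing produces
  expect_equal(max_growth(bt)$status, "infeasible")
})

test_that("producibility screen matches documented toy ground truth", {
  cfg <- fva_config()
  for (nm in c("linear_chain", "branched", "blocked_target", "currency_hub")) {
    m <- generate_toy_model(nm)
    gt <- attr(m, "ground_truth")
    scr <- production_screen(m, cfg, gt$source, gt$targets)
    expect_equal(nrow(scr), 3 * length(gt$targets))
    for (ox in names(cfg$oxygen_levels)) {
      got <- sort(scr$target[scr$oxygen == ox & scr$producible])
      expect_equal(got, sort(gt$producible[[ox]]),
                   info = paste(nm, ox))
    }
    # blocked metabolites fail in all three scenarios
    for (b in gt$blocked) {
      expect_true(all(!scr$producible[scr$target == b]), info = paste(nm, b))
      expect_true(all(scr$max_flux[scr$target == b] <= cfg$producibility_epsilon))
    }
  }
  # linear chain: half the carbon feeds biomass, so max B production is 50
  scr <- production_screen(generate_toy_model("linear_chain"), cfg, "A", "B")
  expect_equal(unique(scr$max_flux), 50)
})

test_that("growth constraint and source bounds act monotonically", {
  m <- generate_toy_model("linear_chain")
  flux_at <- function(frac) {
    cfg <- fva_config(growth_fraction = frac)
    production_screen(m, cfg, "A", "B")$max_flux[1]
  }
  f <- vapply(c(0.25, 0.5, 0.75, 1), flux_at, numeric(1))
  expect_true(all(diff(f) <= 1e-9))   # raising the requirement never helps
  expect_equal(f, c(75, 50, 25, 0))   # hand LP values on the 1:1 chain

  # removing the source never increases target production
  cfg <- fva_config()
  with_src <- production_screen(m, cfg, "A", "B")$max_flux[1]
  closed <- apply_medium(m, cfg, "anoxic", source = NULL)
  g <- max_growth(closed)
  expect_lte(g$mu, with_src)

  # oxygen only relaxes constraints: producible(anoxic) implies
  # producible(aerobic) on the oxygen-free toys
  for (nm in c("linear_chain", "blocked_target", "currency_hub", "branched")) {
    mm <- generate_toy_model(nm)
    gt <- attr(mm, "ground_truth")
    scr <- production_screen(mm, cfg, gt$source, gt$targets)
    anox <- scr$producible[scr$oxygen == "anoxic"]
    aer <- scr$producible[scr$oxygen == "aerobic"]
    expect_true(all(!anox | aer), info = nm)
  }
})

test_that("screen reports zero-growth and control conditions faithfully", {
  # no medium, no usable source: growth is zero, rows flagged
  m <- generate_toy_model("blocked_target")
  scr <- production_screen(m, fva_config(), sources = "U", targets = c("B"))
  expect_true(all(scr$status == "zero_growth"))
  expect_true(all(!scr$producible))

  # control comparison: a target disconnected from the source is producible
  # iff it is producible from the medium alone
  cfg_med <- fva_config(medium = c(A = 10))
  m2 <- generate_toy_model("blocked_target")
  scr2 <- production_screen(m2, cfg_med, sources = "U", targets = "B")
  ctrl <- production_screen(m2, cfg_med, sources = "A", targets = "B")
  expect_equal(unique(scr2$producible), unique(ctrl$producible))
})

test_that("epsilon call clamps solver noise and stays strict", {
  cfg <- fva_config()
  expect_false(flux_epsilon_call(1e-6, cfg))   # strict inequality
  expect_true(flux_epsilon_call(2e-6, cfg))
  expect_false(flux_epsilon_call(-1e-9 + 1e-12, cfg))  # clamped noise
  expect_error(flux_epsilon_call(-1, cfg), "negative")
})

test_that("simplex core agrees with hand-checkable programs", {
  # max x1 + x2 st x1 + 2 x2 <= 4, 3 x1 + x2 <= 6, x >= 0 -> 2.8
  sol <- evogut:::solve_lp_bounded(
    obj = c(1, 1),
    Aeq = matrix(0, 0, 2), beq = numeric(0),
    lb = c(0, 0), ub = c(100, 100),
    Age = rbind(c(-1, -2), c(-3, -1)), bge = c(-4, -6))
  expect_equal(sol$objective, 2.8)
  expect_equal(sol$v, c(1.6, 1.2))

  # infeasible: x = 1 and x = 2 simultaneously
  bad <- evogut:::solve_lp_bounded(
    obj = 1, Aeq = rbind(1, 1), beq = c(1, 2), lb = 0, ub = 10)
  expect_equal(bad$status, "infeasible")
})
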