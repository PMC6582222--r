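one_step <- function(ts, st, name = "s1") {
  data.frame(name = name, dG_TS = ts, dG_step = st)
}

test_that("profile composition builds alternating cumulative levels", {
  p <- compose_profile(one_step(10, 2))
  expect_identical(nrow(p), 3L)
  expect_equal(p$dG, c(0, 10, 2))
  expect_identical(p$kind, c("stationary", "transition", "stationary"))

  # two-step deamination by the B route: highest TS is 9.50 + 54.45
  pb <- compose_profile(data.frame(name = c("1B", "2B"),
                                   dG_TS = c(59.60, 54.45),
                                   dG_step = c(9.50, -8.27)))
  expect_identical(nrow(pb), 5L)
  expect_equal(max(pb$dG[pb$kind == "transition"]), 63.95)

  # amination by the E route composes to the published process row
  pe <- compose_profile(data.frame(name = c("5E", "6E"),
                                   dG_TS = c(54.69, 52.52),
                                   dG_step = c(4.54, 3.87)))
  expect_equal(unname(process_summary(pe)), c(57.06, 8.41))

  expect_error(compose_profile(one_step(1, 1)[0, ]), "at least one")
  expect_error(compose_profile(rbind(one_step(1, 1), one_step(2, 2))),
               "unique")
})

test_that("process summaries use the cumulative-maximum rule", {
  pd <- compose_profile(data.frame(name = c("5D", "6D"),
                                   dG_TS = c(42.51, 53.46),
                                   dG_step = c(-1.69, 18.67)))
  expect_equal(unname(process_summary(pd)), c(51.77, 16.98))

  pc <- compose_profile(data.frame(name = c("3", "4"),
                                   dG_TS = c(56.30, 79.41),
                                   dG_step = c(3.10, 8.85)))
  expect_equal(unname(process_summary(pc)), c(82.51, 11.95))

  # single step: summary is the step itself
  p1 <- compose_profile(one_step(33.3, -4.4))
  expect_equal(unname(process_summary(p1)), c(33.3, -4.4))
})

test_that("rate-determining step is the highest cumulative TS, first on ties", {
  for (phase in c("gas", "solution")) {
    st <- ag_pathway(phase, "step")
    prof <- concat_profiles(lapply(split(st, st$process), compose_profile))
    expect_identical(rate_determining_step(prof), "TS4")
  }
  tie <- compose_profile(data.frame(name = c("a", "b"),
                                    dG_TS = c(20, 15),
                                    dG_step = c(5, 0),
                                    ts_label = c("TSa", "TSb")))
  expect_identical(rate_determining_step(tie), "TSa")   # 20 vs 5 + 15
})

test_that("pathway concatenation recovers the published global energetics", {
  for (cfg in list(list(phase = "gas", act = 74.15),
                   list(phase = "solution", act = 72.88))) {
    st <- ag_pathway(cfg$phase, "process")
    res <- pathway_global(lapply(split(st, st$process), compose_profile))
    expect_equal(res$dG_act_global, cfg$act, tolerance = 1e-12)
    expect_identical(res$rds_label, "TS4")
  }
  # single process in, identical numbers out
  pe <- compose_profile(data.frame(name = c("5E", "6E"),
                                   dG_TS = c(54.69, 52.52),
                                   dG_step = c(4.54, 3.87)))
  solo <- pathway_global(list(pe))
  expect_equal(c(solo$dG_act_global, solo$dG_rxn_global),
               unname(process_summary(pe)))
})

test_that("profiles serialize losslessly and invert to their steps", {
  set.seed(5)
  for (rep in 1:10) {
    n <- sample(1:6, 1)
    steps <- data.frame(name = paste0("s", 1:n),
                        dG_TS = runif(n, -30, 80),
                        dG_step = runif(n, -30, 80))
    p <- compose_profile(steps)
    expect_identical(nrow(p), 2L * n + 1L)
    tab <- profile_to_table(p)
    expect_equal(profile_from_table(tab), p)
    p2 <- compose_profile(profile_steps(p))
    expect_equal(p2$dG, p$dG, tolerance = 1e-12)
  }
})

test_that("composition is additive, associative and matches brute-force levels", {
  set.seed(9)
  for (rep in 1:20) {
    n <- sample(1:10, 1)
    steps <- data.frame(name = paste0("s", 1:n),
                        dG_TS = runif(n, -30, 80),
                        dG_step = runif(n, -30, 80))
    p <- compose_profile(steps)
    # additivity: final level is the sum of step free energies
    expect_equal(p$dG[nrow(p)], sum(steps$dG_step), tolerance = 1e-9)
    # brute-force enumeration oracle
    bl <- brute_levels(steps)
    s <- process_summary(p)
    expect_equal(s[["dG_act"]], max(bl$ts), tolerance = 1e-12)
    expect_equal(s[["dG_rxn"]], bl$stat[n], tolerance = 1e-12)
  }
  # associativity of concatenation
  st <- ag_pathway("gas", "step")
  parts <- lapply(split(st, st$process), compose_profile)
  left  <- concat_profiles(list(concat_profiles(parts[c("A", "C")]),
                                parts[["E"]]))
  right <- concat_profiles(list(parts[["A"]],
                                concat_profiles(parts[c("C", "E")])))
  expect_equal(left$dG, right$dG, tolerance = 1e-12)
  expect_identical(left$label, right$label)
})

test_that("perturbing one step's outcome shifts all downstream levels equally", {
  st <- ag_pathway("gas", "step")
  p0 <- compose_profile(st)
  st$dG_step[2] <- st$dG_step[2] + 3.25
  p1 <- compose_profile(st)
  expect_equal(p1$dG[1:4], p0$dG[1:4])
  expect_equal(p1$dG[5:nrow(p1)], p0$dG[5:nrow(p0)] + 3.25)
})
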