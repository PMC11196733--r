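test_that("model variants expose the declared parameter structure", {
  core <- ibd_model("core")
  expect_length(core$rate_param_names, 5)
  expect_length(core$estimated_initials, 4)
  expect_length(free_param_names(core), 9)
  expect_setequal(core$rate_param_names,
                  c("k_heal", "k_turnB", "k_turnM", "k_turnN", "k_turnT"))

  ext <- ibd_model("extended")
  expect_length(ext$rate_param_names, 6)
  expect_length(ext$estimated_initials, 5)
  expect_true("k_turnE" %in% ext$rate_param_names)

  hum <- ibd_model("human")
  expect_length(hum$rate_param_names, 8)
  expect_setequal(hum$rate_param_names,
                  c("k_cue", "k_act", "k_res", "k_turnB", "k_turnM",
                    "k_turnN", "k_turnT", "k_turnE"))
  expect_equal(unname(hum$fixed_initials["Cue"]), 1)
})

test_that("default wiring is the selected best model and toggles work", {
  core <- ibd_model("core")
  expect_equal(core$stimulus_wiring[["Neutr"]], "DSS")
  expect_equal(core$stimulus_wiring[["Mac"]], "Damage")
  expect_equal(core$stimulus_wiring[["Tcell"]], "Damage")
  expect_equal(core$stimulus_wiring[["Bcell"]], "healedMucosa")

  tog <- ibd_model("core", wiring = c(Mac = "DSS"))
  expect_equal(tog$stimulus_wiring[["Mac"]], "DSS")
  same <- setdiff(names(core$stimulus_wiring), "Mac")
  expect_equal(tog$stimulus_wiring[same], core$stimulus_wiring[same])

  expect_error(ibd_model("nonsense"))
  expect_error(ibd_model("human", wiring = c(Mac = "DSS")), "fixed wiring")
  expect_error(ibd_model("core", wiring = c(Bcell = "DSS")), "only name")
  expect_error(ibd_model("core", wiring = c(Mac = "Cue")), "DSS.*Damage")
})

test_that("wiring enumeration produces all 8 murine candidates exactly once", {
  cands <- enumerate_wirings(ibd_model("core"))
  expect_length(cands, 8)
  expect_equal(vapply(cands, `[[`, integer(1), "candidate_id"), 1:8)
  sigs <- vapply(cands, function(m)
    paste(m$stimulus_wiring[c("Mac", "Neutr", "Tcell")], collapse = "|"),
    character(1))
  expect_length(unique(sigs), 8)
  # every candidate keeps the murine parameter structure
  for (m in cands) {
    expect_length(m$rate_param_names, 5)
    expect_length(m$estimated_initials, 4)
    expect_equal(m$stimulus_wiring[["Bcell"]], "healedMucosa")
  }
  # the winning wiring appears exactly once
  win <- vapply(cands, function(m)
    m$stimulus_wiring[["Neutr"]] == "DSS" &&
      m$stimulus_wiring[["Mac"]] == "Damage" &&
      m$stimulus_wiring[["Tcell"]] == "Damage", logical(1))
  expect_equal(sum(win), 1L)

  expect_length(enumerate_wirings(ibd_model("core"),
                                  toggle = character(0)), 1)
  expect_error(enumerate_wirings(ibd_model("human")), "wiring")
})

test_that("right-hand side matches hand substitution into the equations", {
  core <- ibd_model("core")
  p1 <- c(k_heal = 1, k_turnB = 1, k_turnM = 1, k_turnN = 1, k_turnT = 1)
  st0 <- c(Damage = 0, healedMucosa = 0, Bcell = 0, Mac = 0, Neutr = 0,
           Tcell = 0)
  d <- ode_rhs(core, st0, p1, frede_protocol(), t = 3)
  expect_equal(unname(d["Damage"]), 2.5)
  expect_equal(unname(d[setdiff(names(d), "Damage")]), rep(0, 5))

  st1 <- c(Damage = 0, healedMucosa = 1, Bcell = 10, Mac = 0, Neutr = 0,
           Tcell = 0)
  d1 <- ode_rhs(core, st1, p1, null_protocol(), t = 0)
  expect_equal(unname(d1["Bcell"]), (1 * 1 - 1 / 1) * 10)  # = 0

  hum <- ibd_model("human")
  sth <- stats::setNames(c(1, rep(0, 7)), hum$state_names)
  ph <- c(k_cue = 2, k_act = 1, k_res = 1, k_turnB = 1, k_turnM = 1,
          k_turnN = 1, k_turnT = 1, k_turnE = 1)
  expect_equal(unname(ode_rhs(hum, sth, ph)["Cue"]), -2)

  expect_error(ode_rhs(core, st0, p1[-1], frede_protocol()), "missing")
  expect_error(ode_rhs(core, st0[-1], p1, frede_protocol()), "state names")
})

test_that("cell-state derivatives vanish with the state (positivity)", {
  set.seed(42)
  for (variant in c("core", "extended", "human")) {
    m <- ibd_model(variant)
    cells <- names(default_observables(m))
    for (rep in 1:10) {
      p <- stats::setNames(10^stats::runif(length(m$rate_param_names), -1, 1),
                           m$rate_param_names)
      st <- stats::setNames(stats::runif(length(m$state_names), 0, 10),
                            m$state_names)
      zero_cell <- sample(cells, 1)
      st[zero_cell] <- 0
      d <- ode_rhs(m, st, p, frede_protocol(), t = stats::runif(1, 0, 14))
      expect_identical(unname(d[zero_cell]), 0)
    }
  }
})

test_that("human disease variables relax to their closed-form equilibria", {
  tr <- integrate_model(ibd_model("human"), true_params_human(),
                        null_protocol(), c(0, 60, 120))
  k_act <- true_params_human()[["k_act"]]
  k_res <- true_params_human()[["k_res"]]
  expect_equal(unname(tr$states[3, "ActiveIBD"]), k_act^2,
               tolerance = 1e-6)
  expect_equal(unname(tr$states[3, "Resolution"]), k_res^2,
               tolerance = 1e-6)
})
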