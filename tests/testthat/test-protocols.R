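test_that("hexagonal array geometry matches the applicator", {
  a6 <- build_array("hex6")
  expect_equal(nrow(a6$electrodes), 6)
  d14 <- with(a6$electrodes, sqrt((x[1] - x[4])^2 + (y[1] - y[4])^2))
  expect_equal(d14, 9e-3)  # opposite-center distance
  d12 <- with(a6$electrodes, sqrt((x[1] - x[2])^2 + (y[1] - y[2])^2))
  expect_equal(d12, 4.5e-3)  # adjacent center distance = circumradius
  # edge-to-edge gap between adjacent 1 mm rods
  expect_equal(d12 - 2 * a6$electrodes$contact_radius[1], 2.5e-3)

  a7 <- build_array("hex7")
  expect_equal(nrow(a7$electrodes), 7)
  ctr <- a7$electrodes[a7$electrodes$id == 7, ]
  expect_equal(c(ctr$x, ctr$y), c(0, 0))
  rim1 <- a7$electrodes[1, ]
  expect_equal(sqrt(rim1$x^2 + rim1$y^2), 4.5e-3)  # center-to-rim

  am <- build_array("mea6")
  dm <- with(am$electrodes, sqrt((x[1] - x[2])^2 + (y[1] - y[2])^2))
  expect_equal(dm, 3.5e-3)
  expect_equal(am$electrodes$contact_radius[1], 0.35e-3)

  expect_error(build_array("hex6", contact_radius = 3e-3), "overlap")
})

# enumeration oracle: the set of unordered pairs a protocol should pulse
expected_pairs <- function(array, name) {
  adj <- array$adjacency
  pairs <- lapply(seq_len(nrow(adj)), function(r) sort(adj[r, ]))
  if (name == "alternative")
    pairs <- c(pairs, lapply(seq_len(nrow(array$opposite_pairs)), function(r)
      sort(array$opposite_pairs[r, ])))
  pairs
}

step_pair_keys <- function(protocol) {
  vapply(protocol$steps, function(s)
    paste(sort(c(s$anodes, s$cathodes)), collapse = "-"), character(1))
}

test_that("protocol step counts match the delivery schemes", {
  expect_equal(n_steps(generate_protocol(build_array("hex6"), "alternative")),
               18)
  expect_equal(n_steps(generate_protocol(build_array("mea6"), "mea_lv")), 12)
  expect_equal(n_steps(generate_protocol(build_array("hex7"), "classical")),
               24)
  # oracle: brute-force pair enumeration, two polarities per pair
  for (cs in list(list("hex6", "alternative"), list("hex7", "classical"),
                  list("mea6", "mea_lv"))) {
    arr <- build_array(cs[[1]])
    p <- generate_protocol(arr, cs[[2]])
    expect_equal(n_steps(p), 2 * length(expected_pairs(arr, cs[[2]])))
  }
})

test_that("every pulsed pair appears exactly twice, once per polarity", {
  for (cs in list(list("hex6", "alternative"), list("hex7", "classical"),
                  list("mea6", "mea_lv"))) {
    p <- generate_protocol(build_array(cs[[1]]), cs[[2]])
    keys <- vapply(p$steps, function(s)
      paste(paste(sort(s$anodes), collapse = ","),
            paste(sort(s$cathodes), collapse = ","), sep = ">"), character(1))
    expect_equal(anyDuplicated(keys), 0L)  # no repeated directed step
    undirected <- vapply(p$steps, function(s)
      paste(sort(c(paste(sort(s$anodes), collapse = ","),
                   paste(sort(s$cathodes), collapse = ","))), collapse = "|"),
      character(1))
    expect_true(all(table(undirected) == 2))
  }
})

test_that("central electrode usage distinguishes the two hex protocols", {
  alt <- generate_protocol(build_array("hex6"), "alternative")
  expect_false(any(vapply(alt$steps, function(s)
    7L %in% c(s$anodes, s$cathodes), logical(1))))
  cls <- generate_protocol(build_array("hex7"), "classical")
  uses_center <- vapply(cls$steps, function(s)
    7L %in% c(s$anodes, s$cathodes), logical(1))
  expect_equal(sum(uses_center), 12)
})

test_that("a 60-degree rotation permutes a hex protocol onto itself", {
  perm <- c(2:6, 1L, 7L)  # rotate rim ids by one position, center fixed
  for (cs in list(list("hex6", "alternative"), list("hex7", "classical"))) {
    p <- generate_protocol(build_array(cs[[1]]), cs[[2]])
    key <- function(a, c) paste(paste(sort(a), collapse = ","),
                                paste(sort(c), collapse = ","), sep = ">")
    orig <- sort(vapply(p$steps, function(s)
      key(s$anodes, s$cathodes), character(1)))
    rot <- sort(vapply(p$steps, function(s)
      key(perm[s$anodes], perm[s$cathodes]), character(1)))
    expect_equal(rot, orig)
  }
})

test_that("paired-diagonal reading also yields 18 steps with 2v2 diagonals", {
  p <- generate_protocol(build_array("hex6"), "alternative",
                         diagonal_mode = "paired")
  expect_equal(n_steps(p), 18)
  sizes <- vapply(p$steps, function(s) length(s$anodes), integer(1))
  expect_equal(sum(sizes == 2), 6)
})

test_that("protocol/arrangement mismatch is rejected", {
  expect_error(generate_protocol(build_array("hex6"), "classical"),
               "requires")
  expect_error(generate_protocol(build_array("hex7"), "mea_lv"), "requires")
})

test_that("default pulse trains carry the published parameters", {
  tr <- default_train("alternative")
  expect_equal(tr$Ap, 560)
  expect_equal(tr$Tp, 100e-6)
  expect_equal(tr$NrP, 4L)
  expect_equal(tr$PRR, 5000)
  expect_equal(tr$BRR, 50)
  expect_equal(1 / tr$PRR, 200e-6)  # intra-burst pulse period
  # full alternative protocol delivers 18 x 4 pulses
  expect_equal(n_steps(generate_protocol(build_array("hex6"),
                                         "alternative")) * tr$NrP, 72)
  trm <- default_train("mea_lv")
  expect_equal(trm$Ap, 60)
  expect_equal(trm$Tp, 0.150)
  expect_equal(trm$PRR, 2.82)
})

test_that("pulse-train invariants are enforced", {
  expect_error(pulse_train(100, Tp = 1e-3, NrP = 1, PRR = 5000), "Tp")
  expect_error(pulse_train(100, Tp = 1e-4, NrP = 100, PRR = 5000, NrB = 2,
                           BRR = 100), "burst")
})

test_that("device envelope validation flags out-of-range trains", {
  expect_equal(nrow(validate_against_device(default_train("alternative"))), 0)
  v <- validate_against_device(default_train("mea_lv"))
  expect_setequal(v$parameter, c("Ap", "Tp"))  # 60 V < 80 V; 150 ms > 1 ms
  # boundary values pass inclusively
  edge <- pulse_train(Ap = 80, Tp = 10e-6, NrP = 1, PRR = 0.1)
  expect_equal(nrow(validate_against_device(edge)), 0)
  # upper bounds: the longest pulse exactly fills the 1 kHz period; the
  # highest rate is checked with a short pulse
  edge2 <- pulse_train(Ap = 600, Tp = 1000e-6, NrP = 1, PRR = 1000)
  expect_equal(nrow(validate_against_device(edge2)), 0)
  edge3 <- pulse_train(Ap = 600, Tp = 10e-6, NrP = 1, PRR = 5000)
  expect_equal(nrow(validate_against_device(edge3)), 0)
})

test_that("contact impedance classifier separates the three ranges", {
  expect_equal(as.character(classify_contact_impedance(0)), "too_low")
  expect_equal(as.character(classify_contact_impedance(5050)), "contact")
  expect_equal(as.character(classify_contact_impedance(1e5)), "too_high")
  expect_equal(as.character(classify_contact_impedance(c(50, 200, 2e4))),
               c("too_low", "contact", "too_high"))
  expect_error(classify_contact_impedance(-1), "non-negative")
})

test_that("protocol JSON export round-trips", {
  p <- generate_protocol(build_array("hex6"), "alternative", amplitude = 420)
  f <- tempfile(fileext = ".json")
  protocol_to_json(p, f)
  p2 <- protocol_from_json(f)
  expect_equal(p2$name, p$name)
  expect_equal(length(p2$steps), length(p$steps))
  expect_equal(p2$steps, p$steps)
  expect_equal(p2$train$Ap, p$train$Ap)
})
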