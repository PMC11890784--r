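# Geometry measures: distances, reach scans, kink angles, SASA and
# buried fractions.

test_that("pair distances are Euclidean, per conformer", {
  m <- fixture_model(atom_row("CA", "C", 0, 0, 0, resno = 1),
                     atom_row("CA", "C", 3, 4, 0, chain = "B", resno = 1))
  expect_equal(pair_distance(m, "A:1:CA", "A:1:CA"), 0)
  expect_equal(pair_distance(m, "A:1:CA", "B:1:CA"), 5)
  frames <- list(model_coords(m),
                 rbind(c(0, 0, 0), c(6, 8, 0)))
  d <- pair_distance(fixture_ensemble(m, frames), "A:1:CA", "B:1:CA")
  expect_equal(as.numeric(d), c(5, 10))
  expect_equal(attr(d, "summary")[["mean"]], 7.5)
  # ambiguous selection errors
  m2 <- fixture_model(atom_row("CA", "C", 0, 0, 0, resno = 1),
                      atom_row("CB", "C", 1, 0, 0, resno = 1))
  expect_error(pair_distance(m2, "A:1", "A:1:CA"), "ambiguous")
  expect_error(pair_distance(m2, "A:9:CA", "A:1:CA"), "no atom")
})

test_that("the lysine reach scan applies a strict 12 A boundary", {
  rows <- c(list(atom_row("SG", "S", 0, 0, 0, chain = "E", resno = 85,
                          resname = "CYS")),
            lys_at(5.0, resno = 1), lys_at(11.9, resno = 2),
            lys_at(12.1, resno = 3))
  m <- do.call(fixture_model, rows)
  rep <- lysine_reach_scan(m, "L", "E:85:SG")
  expect_equal(rep$resno, c(1, 2))          # 12.1 excluded: strict "<12"
  expect_equal(rep$min_dist, c(5.0, 11.9))
  expect_true(all(rep$atom_used == "NZ"))
})

test_that("the reach scan reports the union over conformers", {
  rows <- c(list(atom_row("SG", "S", 0, 0, 0, chain = "E", resno = 85,
                          resname = "CYS")),
            lys_at(20, resno = 1))
  m <- do.call(fixture_model, rows)
  base <- model_coords(m)
  near <- base
  near[2:3, 1] <- near[2:3, 1] - 12  # NZ at 8 A in one frame
  ens <- fixture_ensemble(m, list(base, near, base))
  rep <- lysine_reach_scan(ens, "L", "E:85:SG")
  expect_equal(nrow(rep), 1)
  expect_equal(rep$min_dist, 8)
  expect_equal(rep$n_frames_in_range, 1)
})

test_that("the reach scan equals brute-force enumeration on a planted fixture", {
  set.seed(77)
  n_lys <- 12
  dists <- c(runif(7, 3, 11.5), runif(5, 12.5, 30))  # 7 planted in range
  angs <- runif(n_lys, 0, 2 * pi)
  rows <- list(atom_row("SG", "S", 0, 0, 0, chain = "E", resno = 85,
                        resname = "CYS"))
  for (k in seq_len(n_lys)) {
    p <- c(dists[k] * cos(angs[k]), dists[k] * sin(angs[k]), 0)
    rows <- c(rows, list(
      atom_row("CA", "C", p[1], p[2], p[3] + 1.5, chain = "L", resno = k,
               resname = "LYS"),
      atom_row("NZ", "N", p[1], p[2], p[3], chain = "L", resno = k,
               resname = "LYS")))
  }
  m <- do.call(fixture_model, rows)
  rep <- lysine_reach_scan(m, "L", "E:85:SG")
  expect_equal(sort(rep$resno), sort(which(dists < 12)))
  expect_equal(nrow(rep), 7)
  # no lysines -> warned empty report
  expect_warning(empty <- lysine_reach_scan(m, "Z", "E:85:SG"), "no LYS")
  expect_equal(nrow(empty), 0)
})

kink_model <- function(angle_deg, n = 6) {
  th <- angle_deg * pi / 180
  rows <- list()
  for (i in seq_len(n)) {
    rows <- c(rows, list(atom_row("P", "P", i * 4, 0, 0, chain = "A",
                                  resno = i, resname = "DA")))
  }
  for (i in seq_len(n)) {
    rows <- c(rows, list(atom_row("P", "P", i * 4 * cos(th),
                                  i * 4 * sin(th), 0, chain = "B",
                                  resno = i, resname = "DA")))
  }
  do.call(fixture_model, rows)
}

test_that("duplex kink angles match constructed geometries", {
  for (ang in c(180, 140, 90)) {
    m <- kink_model(ang)
    got <- duplex_kink_angle(m, list(chain = "A", resno = 1:6),
                             list(chain = "B", resno = 1:6))
    expect_equal(got, ang, tolerance = 0.5)
  }
  # under-determined arms error
  m2 <- kink_model(140, n = 2)
  expect_error(duplex_kink_angle(m2, list(chain = "A", resno = 1:2),
                                 list(chain = "B", resno = 1:2)),
               "at least 3")
})

test_that("the kink angle is invariant under rigid motions", {
  m <- kink_model(140)
  base <- duplex_kink_angle(m, list(chain = "A", resno = 1:6),
                            list(chain = "B", resno = 1:6))
  th <- 0.83
  rot <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  moved <- sweep(model_coords(m) %*% t(rot), 2, c(13, -7, 22), "+")
  m$atoms$x <- moved[, 1]
  m$atoms$y <- moved[, 2]
  m$atoms$z <- moved[, 3]
  got <- duplex_kink_angle(m, list(chain = "A", resno = 1:6),
                           list(chain = "B", resno = 1:6))
  expect_equal(got, base, tolerance = 1e-6)
})

test_that("SASA matches closed forms and a high-density oracle", {
  # isolated carbon: full probe-expanded sphere 4 pi (1.7 + 1.4)^2
  m1 <- fixture_model(atom_row("C", "C", 0, 0, 0))
  expect_equal(sasa(m1)$total, 4 * pi * 3.1^2, tolerance = 1e-9)
  # far-apart atoms are additive
  m2 <- fixture_model(atom_row("C", "C", 0, 0, 0),
                      atom_row("O", "O", 50, 0, 0, resno = 2))
  expect_equal(sasa(m2)$total, 4 * pi * 3.1^2 + 4 * pi * 2.92^2,
               tolerance = 1e-9)
  # two carbons 2 A apart vs a 1e5-point oracle within 1%
  m3 <- fixture_model(atom_row("C", "C", 0, 0, 0),
                      atom_row("C2", "C", 2, 0, 0, resno = 2))
  a960 <- sasa(m3)$total
  a1e5 <- sasa(m3, n_points = 1e5)$total
  expect_lt(abs(a960 - a1e5) / a1e5, 0.01)
  expect_error(sasa(dccnet:::new_structure_model(m1$atoms[0, ])), "no atoms")
})

test_that("SASA decreases monotonically as partners accumulate", {
  center <- atom_row("C", "C", 0, 0, 0)
  partners <- list(atom_row("C", "C", 3, 0, 0, chain = "B", resno = 1),
                   atom_row("C", "C", -3, 0, 0, chain = "C", resno = 1),
                   atom_row("C", "C", 0, 3, 0, chain = "D", resno = 1))
  prev <- Inf
  for (k in 0:3) {
    m <- do.call(fixture_model, c(list(center), partners[seq_len(k)]))
    a <- sasa(m)$atom_area[1]
    expect_lte(a, prev)
    prev <- a
  }
})

test_that("buried fractions behave at the limits and decompose by partner", {
  # no neighbours -> 0
  m0 <- fixture_model(atom_row("C", "C", 0, 0, 0),
                      atom_row("C", "C", 40, 0, 0, chain = "B", resno = 1))
  expect_equal(buried_fraction(m0, "A")$fraction, 0, tolerance = 1e-12)
  # atom enclosed in a tight cage of partners -> fraction near 1
  shell <- lapply(seq_len(60), function(k) {
    p <- dccnet:::fibonacci_sphere(60)[k, ] * 3.2
    atom_row("C", "C", p[1], p[2], p[3], chain = "B", resno = k)
  })
  mc <- do.call(fixture_model, c(list(atom_row("C", "C", 0, 0, 0)), shell))
  expect_gt(buried_fraction(mc, "A")$fraction, 0.999)
  # two partners burying opposite faces share the decomposition
  m2 <- fixture_model(atom_row("C", "C", 0, 0, 0),
                      atom_row("C", "C", 2.4, 0, 0, chain = "B", resno = 1),
                      atom_row("C", "C", -2.4, 0, 0, chain = "C", resno = 1))
  bf <- buried_fraction(m2, "A")
  expect_gt(bf$fraction, 0)
  expect_equal(sum(bf$partner_share), 1)
  # equal up to sphere-point discretization
  expect_equal(unname(bf$partner_share["B"]),
               unname(bf$partner_share["C"]), tolerance = 0.02)
  expect_error(buried_fraction(m2, "Z"), "no atoms")
})
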