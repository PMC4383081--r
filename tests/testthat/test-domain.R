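test_that("superposition recovers constructed transforms exactly", {
  m <- synthetic_motor_model()
  sp0 <- superpose(m, m)
  expect_equal(sp0$rmsd, 0, tolerance = 1e-9)
  expect_equal(axis_angle(sp0$transform)$angle, 0, tolerance = 1e-6)

  th <- 30 * pi / 180
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
              3, 3, byrow = TRUE)
  m2 <- m
  m2$atoms[, c("x", "y", "z")] <-
    as.matrix(m$atoms[, c("x", "y", "z")]) %*% t(R)
  sp <- superpose(m, m2)
  expect_equal(axis_angle(sp$transform)$angle, 30, tolerance = 1e-6)
  expect_equal(sp$rmsd, 0, tolerance = 1e-8)
})

test_that("superposition rmsd matches a brute-force numeric optimizer", {
  set.seed(17)
  n <- 50
  X <- matrix(rnorm(3 * n, sd = 10), n, 3)
  Y <- X + matrix(rnorm(3 * n, sd = 0.5), n, 3)
  A <- atomic_model(data.frame(chain = "A", resno = 1:n, elety = "CA",
                               x = X[, 1], y = X[, 2], z = X[, 3]))
  B <- atomic_model(data.frame(chain = "A", resno = 1:n, elety = "CA",
                               x = Y[, 1], y = Y[, 2], z = Y[, 3]))
  sp <- superpose(A, B)
  # oracle: direct minimization over the 6 rigid parameters
  obj <- function(p) {
    ax <- p[1:3]; t <- p[4:6]
    th <- sqrt(sum(ax^2))
    R <- if (th < 1e-12) diag(3) else {
      u <- ax / th
      K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
                  3, 3, byrow = TRUE)
      diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
    }
    sqrt(mean(rowSums((sweep(X %*% t(R), 2, t, "+") - Y)^2)))
  }
  opt <- stats::optim(rep(0, 6), obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  expect_equal(sp$rmsd, opt$value, tolerance = 1e-5)
})

test_that("superposition rmsd is invariant under common rigid motion", {
  m <- synthetic_motor_model()
  m2 <- rotate_subdomain(m, default_subdomains()$upper, 9, c(1, 1, 0))
  r1 <- superpose(m, m2, chain = "K")$rmsd
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
              3, 3, byrow = TRUE)
  shift <- c(12, -5, 30)
  for (mm in c("m", "m2")) {
    obj <- get(mm)
    obj$atoms[, c("x", "y", "z")] <-
      sweep(as.matrix(obj$atoms[, c("x", "y", "z")]) %*% t(R), 2, shift, "+")
    assign(mm, obj)
  }
  expect_equal(superpose(m, m2, chain = "K")$rmsd, r1, tolerance = 1e-9)
})

test_that("axis-angle matches the closed form and composes subadditively", {
  set.seed(23)
  rot_of <- function(ax, deg) {
    u <- ax / sqrt(sum(ax^2)); th <- deg * pi / 180
    K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
                3, 3, byrow = TRUE)
    diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  }
  for (i in 1:5) {
    ax <- rnorm(3); deg <- runif(1, 1, 175)
    tr <- rigid_transform(rot_of(ax, deg), rnorm(3))
    aa <- axis_angle(tr)
    R <- tr$rotation
    expect_equal(aa$angle, acos((sum(diag(R)) - 1) / 2) * 180 / pi,
                 tolerance = 1e-6)
  }
  for (i in 1:5) {
    R1 <- rot_of(rnorm(3), runif(1, 5, 80))
    R2 <- rot_of(rnorm(3), runif(1, 5, 80))
    a12 <- axis_angle(rigid_transform(R1 %*% R2))$angle
    a1 <- axis_angle(rigid_transform(R1))$angle
    a2 <- axis_angle(rigid_transform(R2))$angle
    expect_lte(a12, a1 + a2 + 1e-9)
  }
  # identity: flagged undefined axis
  id <- axis_angle(rigid_transform(diag(3)))
  expect_false(id$defined)
  # 22 degrees about z through the origin: full screw decomposition
  aa22 <- axis_angle(rigid_transform(rot_of(c(0, 0, 1), 22)))
  expect_equal(aa22$angle, 22, tolerance = 1e-9)
  expect_equal(abs(aa22$axis[3]), 1, tolerance = 1e-9)
  expect_equal(aa22$point, c(0, 0, 0), tolerance = 1e-6)
})

test_that("subdomain rotations report constructed motions", {
  m <- synthetic_motor_model()
  def <- default_subdomains()
  m2 <- rotate_subdomain(m, def$upper, 11, axis = c(1, 0, 0.5))
  tab <- subdomain_rotations(m, m2, def, frame = list(chain = "T"))
  expect_equal(tab$angle[tab$subdomain == "upper"], 11, tolerance = 0.1)
  expect_lt(tab$angle[tab$subdomain == "n_terminal"], 0.1)
  # identical states: all angles zero
  tab0 <- subdomain_rotations(m, m, def, frame = list(chain = "T"))
  # acos() near its boundary limits the attainable precision
  expect_true(all(tab0$angle < 1e-4))
})

test_that("backbone rmsd is zero for rigid copies and counts selections", {
  m <- synthetic_motor_model()
  m2 <- m
  m2$atoms[, c("x", "y", "z")] <-
    sweep(as.matrix(m$atoms[, c("x", "y", "z")]), 2, c(5, -3, 8), "+")
  expect_equal(backbone_rmsd(m, m2, chain = "K"), 0, tolerance = 1e-9)
  # residue-range selection arithmetic (CA-only model: 1 atom per residue)
  sel <- model_selection(m, chain = "K", resno_range = c(9, 333),
                         elety = "CA")
  n_expected <- sum(m$atoms$chain == "K" & m$atoms$resno >= 9 &
                      m$atoms$resno <= 333)
  expect_equal(nrow(sel$coords), n_expected)
})

test_that("hydrogen bonds follow the heavy-atom distance/angle criteria", {
  atoms <- data.frame(
    chain = "K",
    resno = c(203, 203, 236),
    elety = c("CZ", "NH1", "OE1"),
    x = c(-1.4, 0, 2.3), y = c(-0.9, 0, 1.8), z = 0,
    resid = c("ARG", "ARG", "GLU"))
  m <- atomic_model(atoms)
  pairs <- data.frame(donor_chain = "K", donor_resno = 203,
                      donor_atom = "NH1", acceptor_chain = "K",
                      acceptor_resno = 236, acceptor_atom = "OE1",
                      label = "R203-E236")
  hb <- hbond_check(m, pairs)
  expect_true(hb$present)      # 2.9 A, wide angle
  expect_equal(hb$distance, sqrt(2.3^2 + 1.8^2), tolerance = 1e-9)
  # stretch beyond 3.5 A: absent
  m2 <- m; m2$atoms$x[3] <- 4.0; m2$atoms$y[3] <- 2.0
  expect_false(hbond_check(m2, pairs)$present)
  # missing atoms are skipped and reported
  pairs2 <- rbind(pairs, data.frame(donor_chain = "K", donor_resno = 999,
                                    donor_atom = "NZ", acceptor_chain = "K",
                                    acceptor_resno = 236,
                                    acceptor_atom = "OE1", label = "gone"))
  hb2 <- hbond_check(m2, pairs2)
  expect_equal(attr(hb2, "skipped"), "gone")
})

test_that("the default switch-loop roster covers the closed-network residues", {
  net <- default_hbond_network()
  members <- sort(unique(c(net$donor_resno, net$acceptor_resno)))
  expect_true(all(c(138, 203, 236, 250, 255, 91) %in% members))
})

test_that("clash scan applies the vdW overlap rule and matches brute force", {
  two <- function(d) {
    A <- atomic_model(data.frame(chain = "A", resno = 1, elety = "CA",
                                 element = "C", x = 0, y = 0, z = 0))
    B <- atomic_model(data.frame(chain = "B", resno = 1, elety = "CA",
                                 element = "C", x = d, y = 0, z = 0))
    clash_scan(A, B)
  }
  hit <- two(1.0)      # overlap 1.7 + 1.7 - 1.0 = 2.4 >= 0.4
  expect_equal(nrow(hit$pairs), 1)
  expect_equal(hit$pairs$overlap, 2.4, tolerance = 1e-9)
  expect_equal(nrow(two(3.4)$pairs), 0)   # zero overlap

  set.seed(31)
  mk <- function(n, off) atomic_model(data.frame(
    chain = "A", resno = 1:n, elety = "CA", element = "C",
    x = rnorm(n, off, 6), y = rnorm(n, 0, 6), z = rnorm(n, 0, 6)))
  A <- mk(250, 0); B <- mk(250, 4)
  g <- clash_scan(A, B, method = "grid")
  a <- clash_scan(A, B, method = "all")
  expect_equal(nrow(g$pairs), nrow(a$pairs))
  expect_equal(sort(g$pairs$overlap), sort(a$pairs$overlap),
               tolerance = 1e-12)
})
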