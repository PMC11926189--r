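toy3 <- data.frame(elety = c("N", "CA", "CB"), alt = " ", resid = "ALA",
                   chain = "A", resno = 1,
                   x = c(1.5, 2.5, 3.5), y = c(0.25, 1.25, 2.25),
                   z = c(-1, 0, 1), occ = 1,
                   element = c("N", "C", "C"))

test_that("PDB and mmCIF renderings of a toy model load identically", {
  fp <- writeToyPDB(withr::local_tempfile(fileext = ".pdb"), toy3)
  fc <- writeToyCIF(withr::local_tempfile(fileext = ".cif"), toy3)
  ap <- loadStructure(fp)
  ac <- loadStructure(fc)
  expect_equal(nrow(ap), 3L)
  expect_equal(ap$x, toy3$x)
  expect_equal(ap$y, toy3$y)
  expect_equal(ap$z, toy3$z)
  expect_equal(ap$element, toy3$element)
  expect_equal(ap, ac)
})

test_that("altlocs resolve to highest occupancy; waters and hydrogens drop", {
  at <- rbind(toy3,
              data.frame(elety = "CG", alt = c("A", "B"), resid = "ALA",
                         chain = "A", resno = 1, x = c(9, 9.5), y = 0,
                         z = 0, occ = c(0.4, 0.6), element = "C"),
              data.frame(elety = "O", alt = " ", resid = "HOH", chain = "A",
                         resno = 2, x = 20, y = 20, z = 20, occ = 1,
                         element = "O"),
              data.frame(elety = "H1", alt = " ", resid = "ALA", chain = "A",
                         resno = 1, x = 2, y = 2, z = 2, occ = 1,
                         element = "H"))
  f <- writeToyPDB(withr::local_tempfile(fileext = ".pdb"), at)
  a <- loadStructure(f)
  expect_equal(nrow(a), 4L)                       # 3 + resolved CG
  cg <- a[a$elety == "CG", ]
  expect_equal(cg$x, 9.5)                         # occupancy 0.6 wins
  expect_false(any(a$resid == "HOH"))
  expect_false(any(a$element == "H"))
})

test_that("unknown elements warn and fall back to the default radius", {
  a <- toyAtomTable("A", 1, "X1", "XX", 0, 0, 0)
  expect_warning(ar <- sasa(a), "unknown element")
  expect_equal(suppressWarnings(sasa(a)), 4 * pi * (1.70 + 1.4)^2,
               tolerance = 0.01)
})

test_that("Kabsch superposition: identity, rigid invariance, degeneracy", {
  set.seed(401)
  A <- matrix(rnorm(90), 30, 3)
  expect_equal(superposeRmsd(A, A)$rmsd, 0, tolerance = 1e-12)
  R <- eulerToRotation(12, 78, -140)
  B <- A %*% t(R) + matrix(rep(c(5, -3, 2), each = 30), 30)
  fit <- superposeRmsd(A, B)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  expect_equal(sweep(A %*% fit$rotation, 2, fit$translation, "+"), B,
               tolerance = 1e-9)
  # invariance to global motion of either input
  G <- eulerToRotation(-33, 21, 101)
  noisy <- B + matrix(rnorm(90, 0, 0.5), 30)
  expect_equal(superposeRmsd(A, noisy)$rmsd,
               superposeRmsd(A %*% t(G), noisy %*% t(G))$rmsd,
               tolerance = 1e-9)
  expect_error(superposeRmsd(A[1:2, ], B[1:2, ]), "at least 3")
  line <- cbind(1:10, 2 * (1:10), -1 * (1:10))
  expect_error(superposeRmsd(line, line + 1), "collinear|ill-conditioned")
})

test_that("Kabsch RMSD matches a direct numerical optimiser on noisy data", {
  set.seed(402)
  A <- matrix(rnorm(240), 80, 3)
  R <- eulerToRotation(40, 60, -20)
  B <- A %*% t(R) + matrix(rep(c(1, 2, 3), each = 80), 80) +
    matrix(rnorm(240, 0, 0.5), 80)
  fit <- superposeRmsd(A, B)
  obj <- function(par) {
    Rp <- eulerToRotation(par[1], par[2], par[3])
    sqrt(mean(rowSums((sweep(A %*% t(Rp), 2, par[4:6], "+") - B)^2)))
  }
  opt <- optim(c(40, 60, -20, 1, 2, 3), obj, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-12))
  expect_lte(fit$rmsd, opt$value + 1e-6)      # Kabsch is the optimum
  expect_equal(fit$rmsd, opt$value, tolerance = 1e-3)
})

test_that("residue pairing restricts to the range modelled in both chains", {
  zz <- c(0, 1, 0.5, -1, 2, 0, 1.5, -0.5, 1, 0.25, 3, -2)
  a <- rbind(toyAtomTable("A", 1:10, "CA", "C", 1:10, (1:10)^1.5, zz[1:10]),
             toyAtomTable("B", 4:12, "CA", "C", 4:12 + 0.5,
                          (4:12)^1.5 + 1, zz[4:12]))
  pr <- pairCommonResidues(a, "A", "B")
  expect_equal(pr$resno, 4:10)
  expect_equal(superposeRmsd(pr$coordsA, pr$coordsB)$rmsd, 0,
               tolerance = 1e-9)
  expect_error(pairCommonResidues(a[a$chain == "A", ], "A", "B"),
               "fewer than 3")
})

test_that("SASA matches closed forms: isolated sphere, engulfed atom, two-sphere cap", {
  one <- toyAtomTable("A", 1, "C1", "C", 0, 0, 0)
  expect_equal(sasa(one), 4 * pi * 3.1^2, tolerance = 4 * pi * 3.1^2 * 0.01)

  # atom fully inside another expanded sphere has zero accessibility
  pair <- rbind(toyAtomTable("A", 1, "P1", "P", 0, 0, 0),       # r+p = 3.2
                toyAtomTable("A", 2, "O1", "O", 0.1, 0, 0))     # r+p = 2.92
  expect_equal(sasa(pair)[2], 0)

  # two identical C spheres at distance d: lost area = 2 spherical caps
  for (d in c(1.0, 2.0, 4.0)) {
    two <- rbind(toyAtomTable("A", 1, "C1", "C", 0, 0, 0),
                 toyAtomTable("B", 1, "C1", "C", d, 0, 0))
    r <- 3.1
    capArea <- 2 * pi * r * (r - d / 2)
    got <- sasa(two, nPoints = 2000)
    expect_equal(sum(got), 2 * (4 * pi * r^2 - capArea),
                 tolerance = 2 * (4 * pi * r^2) * 0.02)
    expect_lt(sum(got), 2 * 4 * pi * r^2)     # monotonicity
  }
})

twoChainToy <- function() {
  set.seed(403)
  helixish <- function(chain, x0) {
    n <- 12
    toyAtomTable(chain, rep(1:4, each = 3),
                 rep(c("N", "CA", "C"), 4),
                 rep(c("N", "C", "C"), 4),
                 x0 + seq(0, 5.5, length.out = n),
                 2 * sin(seq(0, 3 * pi, length.out = n)),
                 2 * cos(seq(0, 3 * pi, length.out = n)))
  }
  rbind(helixish("A", 0), helixish("B", 3.2))
}

test_that("buried area: zero when distant, additive bound, refinement-stable", {
  far <- rbind(toyAtomTable("A", 1, "CA", "C", 0, 0, 0),
               toyAtomTable("B", 1, "CA", "C", 100, 0, 0))
  expect_equal(buriedArea(far, "A")@buriedTotal, 0)

  at <- twoChainToy()
  ir <- buriedArea(at, "A", nPoints = 960)
  expect_gt(ir@buriedTotal, 0)
  expect_equal(names(ir@buriedByChain), "B")
  expect_equal(unname(ir@buriedByChain["B"]), ir@buriedTotal,
               tolerance = 1e-9)
  # SASA additivity bound
  sAB <- sum(sasa(at)); sA <- sum(sasa(at[at$chain == "A", ]))
  sB <- sum(sasa(at[at$chain == "B", ]))
  expect_lte(sAB, sA + sB)
  # high-density refinement agrees within 2%
  hi <- buriedArea(at, "A", nPoints = 10000)
  expect_lt(abs(ir@buriedTotal - hi@buriedTotal) / hi@buriedTotal, 0.02)
})

test_that("per-partner buried areas split a multi-chain interface sensibly", {
  at <- rbind(toyAtomTable("Q", 1, "CA", "C", 0, 0, 0),
              toyAtomTable("B", 1, "CA", "C", 3, 0, 0),
              toyAtomTable("C", 1, "CA", "C", -3, 0, 0))
  ir <- buriedArea(at, "Q")
  expect_setequal(names(ir@buriedByChain), c("B", "C"))
  expect_true(all(ir@buriedByChain > 0))
  # symmetric geometry gives symmetric shares
  expect_equal(unname(ir@buriedByChain["B"]), unname(ir@buriedByChain["C"]),
               tolerance = 0.05 * unname(ir@buriedByChain["B"]))
})

test_that("contact residues: boundary behaviour, brute force, monotonicity", {
  at <- rbind(toyAtomTable("A", 1, "CA", "C", 0, 0, 0),
              toyAtomTable("A", 2, "CA", "C", 10, 0, 0),
              toyAtomTable("B", 1, "CA", "C", 3.9, 0, 0),
              toyAtomTable("B", 2, "CA", "C", 10, 4.1, 0))
  cr <- contactResidues(at, "A", cutoff = 4.0)
  expect_equal(cr$resno, 1L)                       # 3.9 in, 4.1 out
  crWide <- contactResidues(at, "A", cutoff = 4.2)
  expect_equal(crWide$resno, c(1L, 2L))            # grows with cutoff
  expect_true(all(cr$resno %in% crWide$resno))

  none <- contactResidues(at[at$chain == "A", ], "A")
  expect_equal(nrow(none), 0L)

  # brute-force all-pairs scan agrees on the toy two-chain model
  toy <- twoChainToy()
  got <- contactResidues(toy, "A", cutoff = 4.0)$resno
  q <- toy[toy$chain == "A", ]; p <- toy[toy$chain == "B", ]
  want <- sort(unique(q$resno[vapply(seq_len(nrow(q)), function(i)
    any(sqrt((q$x[i] - p$x)^2 + (q$y[i] - p$y)^2 +
               (q$z[i] - p$z)^2) <= 4.0), logical(1))]))
  expect_equal(got, want)
})

test_that("binder classification splits residue sets by site", {
  ca <- data.frame(resno = c(1, 2, 3, 5))
  cb <- data.frame(resno = c(2, 5, 9))
  out <- classifyBinders(ca, cb)
  expect_equal(out$shared, c(2, 5))
  expect_equal(out$onlyA, c(1, 3))
  expect_equal(out$onlyB, 9)
})
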