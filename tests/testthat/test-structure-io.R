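test_that("readPDB returns filtered ATOM records of the requested model", {
    path <- writeThreeResiduePDB()
    s <- readPDB(path)
    expect_s4_class(s, "PDBStructure")
    expect_equal(nrow(s@atoms), 15)
    expect_equal(sum(s@atoms$elety == "CA"), 3)

    ## hydrogens, waters and HETATM records are dropped
    lines <- c(threeResidueLines(),
               pdbLine(90, "H", "GLY", "A", 1, c(0, 1, 1), "H"),
               pdbLine(91, "O", "HOH", "A", 9, c(20, 0, 0), "O",
                       record = "HETATM"),
               "END")
    p2 <- tempfile(fileext = ".pdb")
    writeLines(lines, p2)
    expect_equal(nrow(readPDB(p2)@atoms), 15)
})

test_that("readPDB selects the requested model of a multi-model file", {
    p <- tempfile(fileext = ".pdb")
    writeLines(c("MODEL        1",
                 pdbLine(1, "CA", "GLY", "A", 1, c(0, 0, 0), "C"),
                 pdbLine(2, "CA", "GLY", "A", 2, c(3.8, 0, 0), "C"),
                 "ENDMDL",
                 "MODEL        2",
                 pdbLine(1, "CA", "GLY", "A", 1, c(0.5, 0, 0), "C"),
                 pdbLine(2, "CA", "GLY", "A", 2, c(4.3, 0, 0), "C"),
                 "ENDMDL", "END"), p)
    s2 <- readPDB(p, modelIndex = 2)
    expect_equal(s2@atoms$x, c(0.5, 4.3))
    expect_error(readPDB(p, modelIndex = 3), "out of range")
    expect_error(readPDB(tempfile()), "not found")
})

test_that("alternate locations other than blank/'A' are excluded", {
    p <- tempfile(fileext = ".pdb")
    writeLines(c(pdbLine(1, "CA", "GLY", "A", 1, c(0, 0, 0), "C",
                         altloc = "A"),
                 pdbLine(2, "CA", "GLY", "A", 1, c(0.4, 0, 0), "C",
                         altloc = "B"),
                 pdbLine(3, "CA", "GLY", "A", 2, c(3.8, 0, 0), "C"),
                 "END"), p)
    s <- readPDB(p)
    expect_equal(nrow(s@atoms), 2)       # altloc B dropped
    expect_equal(s@atoms$x[1], 0)
})

test_that("selectNodes builds calpha and heavy-atom node sets", {
    s <- readPDB(writeThreeResiduePDB())
    ca <- selectNodes(s, "calpha")
    expect_equal(nodeCount(ca), 3)
    expect_equal(length(unique(resKeys(ca))), 3)
    heavy <- selectNodes(s, "heavy_atom")
    expect_equal(nodeCount(heavy), 15)   # 4 + 5 + 6 heavy atoms
    expect_equal(unique(heavy@atomNames[resKeys(heavy) == "A|1|"]),
                 c("N", "CA", "C", "O"))

    ## node order is deterministic across reads
    ca2 <- selectNodes(readPDB(writeThreeResiduePDB()), "calpha")
    expect_identical(resKeys(ca), resKeys(ca2))
    expect_identical(coords(ca), coords(ca2))
})

test_that("selectNodes reports residues without a CA atom", {
    p <- tempfile(fileext = ".pdb")
    writeLines(c(pdbLine(1, "CA", "GLY", "A", 1, c(0, 0, 0), "C"),
                 pdbLine(2, "N", "GLY", "A", 2, c(3.8, 0, 0), "N"),
                 pdbLine(3, "CA", "GLY", "A", 3, c(7.6, 0, 0), "C"),
                 "END"), p)
    expect_error(selectNodes(readPDB(p), "calpha"), "A\\|2\\|")
})

test_that("readTrajectory parses multi-model PDB and frames tables", {
    fx <- makeBeadProtein(fixtureSpec(nDomains = 1L, beadsPerDomain = 4L,
                                      seed = 3))
    ms <- decomposeModes(buildKirchhoff(fx$model, rc = 7.5))
    traj <- sampleGNMTrajectory(ms, coords(fx$model), 5, seed = 3)
    mm <- tempfile(fileext = ".pdb")
    writeMultiModelPDB(traj, mm)
    rt <- readTrajectory(mm, "multi_model_pdb")
    expect_equal(dim(rt@frames), c(5, 4, 3))
    expect_equal(rt@frames, traj@frames, tolerance = 1e-3)

    ft <- tempfile(fileext = ".txt")
    traj10 <- sampleGNMTrajectory(ms, coords(fx$model), 10, seed = 4)
    writeFramesTable(traj10, ft)
    rt2 <- readTrajectory(ft, "frames_table")
    expect_equal(dim(rt2@frames), c(10, 4, 3))
    expect_equal(rt2@frames, traj10@frames, tolerance = 1e-6)
})

test_that("a frame with a missing atom is reported by frame number", {
    lines <- c()
    for (f in 1:3) {
        lines <- c(lines, sprintf("MODEL     %4d", f))
        nAtoms <- if (f == 3) 2 else 3
        for (i in seq_len(nAtoms))
            lines <- c(lines, pdbLine(i, "CA", "GLY", "A", i,
                                      c(3.8 * (i - 1) + 0.1 * f, 0, 0),
                                      "C"))
        lines <- c(lines, "ENDMDL")
    }
    p <- tempfile(fileext = ".pdb")
    writeLines(c(lines, "END"), p)
    expect_error(readTrajectory(p, "multi_model_pdb"), "frame 3")

    ## single-frame files are rejected too
    p1 <- tempfile(fileext = ".pdb")
    writeLines(c("MODEL        1",
                 pdbLine(1, "CA", "GLY", "A", 1, c(0, 0, 0), "C"),
                 "ENDMDL", "END"), p1)
    expect_error(readTrajectory(p1, "multi_model_pdb"), "at least 2")
})

test_that("coarse-model PDB round trip preserves coordinates to 1e-3 A", {
    fx <- makeBeadProtein(fixtureSpec(seed = 5))
    p <- tempfile(fileext = ".pdb")
    writeCoarsePDB(fx$model, p)
    back <- selectNodes(readPDB(p), "calpha")
    expect_equal(coords(back), coords(fx$model), tolerance = 2e-3,
                 ignore_attr = TRUE)
    expect_identical(resKeys(back), resKeys(fx$model))
})
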