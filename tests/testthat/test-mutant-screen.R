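test_that("residue-level reduction extracts C-alpha correlations", {
    ## every residue a single atom: reduction is the identity
    fx <- makeBeadProtein(fixtureSpec(seed = 2))
    dcc <- gnmCorrelations(fx$model, nModes = 10)
    red <- residueLevelDCC(dcc, fx$model)
    expect_equal(red@matrix, dcc@matrix)

    ## two residues x two atoms with exact block correlations
    cval <- 0.4
    m <- matrix(cval, 4, 4)
    m[1:2, 1:2] <- 1
    m[3:4, 3:4] <- 1
    allatom <- new("CorrelationMatrix", matrix = m, source = "gnm",
                   nModes = 5L, resKeys = character())
    model <- new("CoarseModel",
                 coords = rbind(c(0, 0, 0), c(1.5, 0, 0),
                                c(5, 0, 0), c(6.5, 0, 0)),
                 resKeys = c("A|1|", "A|1|", "A|2|", "A|2|"),
                 atomNames = c("CA", "CB", "CA", "CB"),
                 selectionMode = "heavy_atom")
    red2 <- residueLevelDCC(allatom, model)
    expect_equal(red2@matrix, matrix(c(1, cval, cval, 1), 2))
    expect_identical(resKeys(red2), c("A|1|", "A|2|"))
    ## averaging reduction agrees on block-constant input
    redAvg <- residueLevelDCC(allatom, model, method = "average")
    expect_equal(redAvg@matrix, red2@matrix, tolerance = 1e-12)

    noCA <- model
    noCA@atomNames <- c("CB", "CG", "CA", "CB")
    expect_error(residueLevelDCC(allatom, noCA), "no CA atom")
})

test_that("ddG classification matches the reference thresholds", {
    expect_identical(classifyStability(-4.7), "unstable")
    expect_identical(classifyStability(0.0), "stable")
    expect_true(is.na(classifyStability(-2.6)))   # boundary is ambiguous

    tab <- t4MutantTable()
    expect_equal(nrow(tab), 17)                   # 16 mutants + wild-type
    expect_equal(sum(tab$stability == "unstable"), 8)
    boundary <- tab[tab$ddG == -2.6, ]
    expect_setequal(boundary$stability, c("unstable", "stable"))
    nonBoundary <- tab[tab$ddG != -2.6 & tab$pdb_id != "4s0w", ]
    expect_identical(classifyStability(nonBoundary$ddG),
                     nonBoundary$stability)
})

test_that("a mutant identical to the wild-type scores kappa 1 everywhere", {
    fx <- makeBeadProtein(fixtureSpec(seed = 11))
    wt <- tempfile(fileext = ".pdb")
    writeCoarsePDB(fx$model, wt)
    rep <- screenMutants(readPDB(wt),
                         list(list(id = "same", structure = readPDB(wt),
                                   stability = "stable")),
                         subsets = c(5, 10), ncRange = 2:5,
                         mode = "calpha")
    expect_true(all(rep@perMutant$kappa == 1))
    expect_true(all(rep@medians$kappa == 1))
})

test_that("inter-domain rewiring shifts communities more than an intra edit", {
    fx <- makeBeadProtein(fixtureSpec(seed = 11))
    co <- coords(fx$model)
    ## intra: a nudge too small to change any contact
    intra <- perturbContacts(fx$model,
                             list(list(bead = 5, to = co[5, ] + c(0.05, 0, 0))))
    expect_identical(as.matrix(buildKirchhoff(intra)),
                     as.matrix(buildKirchhoff(fx$model)))
    ## inter: pull the domain-2 bridge bead into the linker gap,
    ## adding inter-domain contacts
    d <- as.matrix(dist(co))
    d[1:10, 1:10] <- Inf
    d[11:20, 11:20] <- Inf
    bridge <- max(which(d == min(d), arr.ind = TRUE)[1, ])
    inter <- perturbContacts(fx$model,
                             list(list(bead = bridge,
                                       to = co[bridge, ] + c(-3.5, 0, 0))))
    wt <- tempfile(fileext = ".pdb")
    writeCoarsePDB(fx$model, wt)
    paths <- sapply(list(intra = intra, inter = inter), function(m) {
        p <- tempfile(fileext = ".pdb")
        writeCoarsePDB(m, p)
        p
    })
    rep <- screenMutants(readPDB(wt),
                         list(list(id = "intra",
                                   structure = readPDB(paths["intra"]),
                                   stability = "stable"),
                              list(id = "inter",
                                   structure = readPDB(paths["inter"]),
                                   stability = "unstable")),
                         subsets = c(5, 10), ncRange = 2:4,
                         mode = "calpha")
    pm <- rep@perMutant
    kIntra <- pm$kappa[pm$id == "intra" & pm$nc == 2 & pm$nModes == 5]
    kInter <- pm$kappa[pm$id == "inter" & pm$nc == 2 & pm$nModes == 5]
    expect_equal(kIntra, 1)
    expect_lt(kInter, kIntra)

    ## class medians are invariant to mutant input order
    rep2 <- screenMutants(readPDB(wt),
                          list(list(id = "inter",
                                    structure = readPDB(paths["inter"]),
                                    stability = "unstable"),
                               list(id = "intra",
                                    structure = readPDB(paths["intra"]),
                                    stability = "stable")),
                          subsets = c(5, 10), ncRange = 2:4,
                          mode = "calpha")
    expect_equal(rep@medians, rep2@medians)
})

test_that("structures sharing too few residues are rejected", {
    fx <- makeBeadProtein(fixtureSpec(seed = 11))
    wt <- tempfile(fileext = ".pdb")
    writeCoarsePDB(fx$model, wt)
    ## a fragment covering only 8 of 20 residues
    frag <- new("CoarseModel", coords = coords(fx$model)[1:8, ],
                resKeys = resKeys(fx$model)[1:8],
                atomNames = rep("CA", 8), selectionMode = "calpha")
    fp <- tempfile(fileext = ".pdb")
    writeCoarsePDB(frag, fp)
    expect_error(
        screenMutants(readPDB(wt),
                      list(list(id = "frag", structure = readPDB(fp),
                                stability = "stable")),
                      subsets = 5, ncRange = 2:3, mode = "calpha"),
        "50%")
})

test_that("the mutant manifest loader reports missing structures", {
    man <- tempfile(fileext = ".csv")
    writeLines(c("pdb_id,path,mutations,ddG,stability_class",
                 "3c80,missing_a.pdb,R96Y,-4.7,Unstable",
                 "3c81,missing_b.pdb,K85A,-0.6,Stable"), man)
    expect_error(readMutantManifest(man), "3c80.*3c81")

    fx <- makeBeadProtein(fixtureSpec(seed = 1))
    dir <- tempfile(); dir.create(dir)
    writeCoarsePDB(fx$model, file.path(dir, "wt.pdb"))
    man2 <- file.path(dir, "man.csv")
    writeLines(c("pdb_id,path,mutations,ddG,stability_class",
                 "wt,wt.pdb,,0.0,Stable"), man2)
    loaded <- readMutantManifest(man2)
    expect_length(loaded, 1)
    expect_identical(loaded[[1]]$stability, "stable")
    expect_s4_class(loaded[[1]]$structure, "PDBStructure")
})
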