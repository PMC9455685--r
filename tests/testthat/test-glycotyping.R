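make_mfi <- function(df, control = "MPB49") MFIExperiment(df, control)

test_that("summarizeMFI computes replicate means and sample SDs", {
    df <- data.frame(population = "p1", scfv = "s1", replicate = 1:3,
                     mfi = c(10, 20, 30))
    out <- summarizeMFI(make_mfi(df, control = NA))
    expect_equal(out$mean, 20)
    expect_equal(out$sd, 10)
    expect_false(out$singleReplicate)
    one <- summarizeMFI(make_mfi(data.frame(
        population = "p1", scfv = "s1", replicate = 1, mfi = 7),
        control = NA))
    expect_equal(one$mean, 7)
    expect_equal(one$sd, 0)
    expect_true(one$singleReplicate)
})

test_that("summarizeMFI matches a naive per-cell loop on random tables", {
    set.seed(21)
    df <- expand.grid(population = paste0("p", 1:4),
                      scfv = paste0("s", 1:3), replicate = 1:3,
                      stringsAsFactors = FALSE)
    df$mfi <- stats::rlnorm(nrow(df), log(500), 0.5)
    out <- summarizeMFI(make_mfi(df, control = NA))
    for (i in seq_len(nrow(out))) {
        v <- df$mfi[df$population == out$population[i] &
                    df$scfv == out$scfv[i]]
        expect_equal(out$mean[i], mean(v))
        expect_equal(out$sd[i], stats::sd(v))
    }
    # replicate order never changes the summary
    out2 <- summarizeMFI(make_mfi(df[rev(seq_len(nrow(df))), ],
                                  control = NA))
    key <- function(d) d[order(d$population, d$scfv), c("mean", "sd")]
    expect_equal(key(out2), key(out), ignore_attr = TRUE)
})

test_that("percentiles hit their endpoints, average ties and ignore scale", {
    df <- data.frame(population = rep(c("p1", "p2", "p3"), each = 1),
                     scfv = "s1", replicate = 1, mfi = c(5, 50, 500))
    x <- make_mfi(df, control = NA)
    expect_equal(unname(mfiPercentile(x)[, "s1"]), c(0, 50, 100))
    # two tied populations among three share the average rank
    dft <- data.frame(population = c("p1", "p2", "p3"), scfv = "s1",
                      replicate = 1, mfi = c(10, 10, 99))
    pt <- mfiPercentile(make_mfi(dft, control = NA))[, "s1"]
    expect_equal(unname(pt), c(25, 25, 100))
    # invariance under a strictly increasing transform
    dfl <- df; dfl$mfi <- log(dfl$mfi)
    expect_equal(mfiPercentile(make_mfi(dfl, control = NA)),
                 mfiPercentile(x))
    # undefined with a single population
    expect_error(mfiPercentile(make_mfi(df[1, ], control = NA)),
                 "two populations")
})

test_that("per-replicate and replicate-mean percentile paths both work", {
    set.seed(31)
    df <- expand.grid(population = paste0("p", 1:5),
                      scfv = paste0("s", 1:2), replicate = 1:3,
                      stringsAsFactors = FALSE)
    df$mfi <- stats::rlnorm(nrow(df), log(300), 1)
    x <- make_mfi(df, control = NA)
    pr <- mfiPercentile(x, perReplicate = TRUE)
    pm <- mfiPercentile(x, perReplicate = FALSE)
    expect_identical(dim(pr), dim(pm))
    expect_true(all(pr >= 0 & pr <= 100))
    # on replicate means each scFv column spans the 0/100 endpoints
    expect_true(all(apply(pm, 2, min) == 0 & apply(pm, 2, max) == 100))
})

test_that("control-relative normalization subtracts, ratios and clamps", {
    df <- rbind(
        data.frame(population = "p1", scfv = "s1", replicate = 1,
                   mfi = 100),
        data.frame(population = "p1", scfv = "s2", replicate = 1,
                   mfi = 10),
        data.frame(population = "p1", scfv = "MPB49", replicate = 1,
                   mfi = 20))
    x <- make_mfi(df)
    sub <- controlRelative(x, "subtract")
    m <- SummarizedExperiment::assay(sub, "mfi")
    expect_false("MPB49" %in% rownames(m))
    expect_equal(m["s1", 1], 100 - 20, ignore_attr = TRUE)
    expect_equal(m["s2", 1], 0, ignore_attr = TRUE)  # clamped
    expect_identical(S4Vectors::metadata(sub)$clamped, 1L)
    rat <- controlRelative(x, "ratio")
    expect_equal(SummarizedExperiment::assay(rat, "mfi")["s1", 1], 5,
                 ignore_attr = TRUE)
    # missing control
    y <- make_mfi(df[df$scfv != "MPB49", ])
    expect_error(controlRelative(y, "subtract"), "MPB49")
})

test_that("the high/low gate partitions by count with stable tie-breaks", {
    set.seed(8)
    v <- sample(seq_len(1000))  # distinct
    g <- gateHighLow(v, 0.5, 0.5)
    tab <- table(gateLabels(g))
    expect_identical(as.vector(tab), c(500L, 500L, 0L))
    expect_true(min(v[gateLabels(g) == "high"]) >
                max(v[gateLabels(g) == "low"]))
    g2 <- gateHighLow(seq_len(10), 0.4, 0.4)
    expect_identical(as.vector(table(gateLabels(g2))), c(4L, 4L, 2L))
    # all-equal values: first-by-input-order half labeled high
    ge <- gateHighLow(rep(1, 10), 0.5, 0.5)
    expect_identical(as.character(gateLabels(ge)[1:5]), rep("high", 5))
    expect_identical(as.character(gateLabels(ge)[6:10]), rep("low", 5))
    expect_error(gateHighLow(v, 0.6, 0.5), "exceed 1")
    expect_error(gateHighLow(v[1], 0.5, 0.5), "at least two")
    # thresholds bracket the gate
    expect_true(gateThresholds(g)[["highMin"]] >
                gateThresholds(g)[["lowMax"]])
})

test_that("binding distributions normalize to unit row sums", {
    df <- data.frame(population = rep(paste0("R", 1:4), each = 1),
                     scfv = "s1", replicate = 1, mfi = c(30, 30, 30, 10))
    x <- make_mfi(df, control = NA)
    bd <- bindingDistribution(x, paste0("R", 1:4))
    expect_equal(unname(bd["s1", ]), c(0.3, 0.3, 0.3, 0.1))
    expect_equal(unname(bindingDistribution(x, "R1")["s1", ]), 1)
    expect_error(bindingDistribution(x, "R9"), "unknown population")
    # all-zero scFv profile is NA and warned about
    dz <- rbind(df, data.frame(population = paste0("R", 1:4),
                               scfv = "s0", replicate = 1, mfi = 0))
    expect_warning(bz <- bindingDistribution(make_mfi(dz, control = NA)),
                   "all-zero")
    expect_true(all(is.na(bz["s0", ])))
    expect_equal(sum(bz["s1", ]), 1)
    # property: random tables always give unit row sums
    set.seed(77)
    dr <- expand.grid(population = paste0("p", 1:5),
                      scfv = paste0("s", 1:4), replicate = 1:2,
                      stringsAsFactors = FALSE)
    dr$mfi <- stats::rlnorm(nrow(dr))
    br <- bindingDistribution(make_mfi(dr, control = NA))
    expect_true(all(abs(rowSums(br) - 1) < 1e-12))
})

test_that("glycotype distances are symmetric, zero on self and oracle-exact", {
    set.seed(55)
    df <- expand.grid(population = paste0("p", 1:4),
                      scfv = paste0("s", 1:5), replicate = 1:3,
                      stringsAsFactors = FALSE)
    df$mfi <- stats::rlnorm(nrow(df), log(400), 0.7)
    prof <- glycotypeProfiles(make_mfi(df, control = NA))
    v <- profileValues(prof)
    for (metric in c("euclidean", "correlation")) {
        D <- glycotypeDistance(prof, metric = metric)
        expect_equal(unname(diag(D)), rep(0, 4), tolerance = 1e-12)
        expect_equal(D, t(D))
        # naive double loop oracle
        for (i in 1:4) for (j in 1:4) {
            d <- if (metric == "euclidean")
                sqrt(sum((v[i, ] - v[j, ])^2))
            else 1 - stats::cor(v[i, ], v[j, ])
            expect_equal(unname(D[i, j]), d, tolerance = 1e-12)
        }
    }
    # perfectly anti-correlated profiles have correlation distance 2
    a <- c(s1 = 1, s2 = 2, s3 = 3)
    b <- c(s1 = 3, s2 = 2, s3 = 1)
    expect_equal(glycotypeDistance(a, b, metric = "correlation"), 2)
    expect_equal(glycotypeDistance(a, a), 0)
    expect_error(glycotypeDistance(a, c(s1 = 1, s9 = 2, s3 = 3)),
                 "same scFv panel")
    # clustering is deterministic average linkage over the same distances
    hc <- clusterGlycotypes(prof)
    expect_s3_class(hc, "hclust")
    expect_identical(hc$method, "average")
    expect_identical(clusterGlycotypes(prof)$merge, hc$merge)
})
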