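#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise level in (0,1).
#' @param nTests number of tests (>= 1); screening 36 candidate mediators
#'   at alpha = 0.05 gives 0.05/36 = 0.0014.
#' @return alpha / nTests.
#' @examples
#' bonferroniThreshold(0.05, 36)
#' @export
bonferroniThreshold <- function(alpha = 0.05, nTests) {
    if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
        stop("alpha must be in (0,1)")
    if (!is.numeric(nTests) || nTests < 1)
        stop("nTests must be >= 1")
    alpha / nTests
}

.resolveStats <- function(x, what) {
    if (is.character(x)) readSummaryStats(x)
    else if (is(x, "SummaryStats")) x
    else if (is.data.frame(x)) SummaryStats(x)
    else stop("cannot interpret ", what, " input")
}

.subsetStats <- function(x, ids) {
    d <- asSummaryData(x)
    new("SummaryStats", data = d[d$SNP %in% ids, , drop = FALSE])
}

#' Run the full two-step MR study
#'
#' Orchestrates the whole design on one exposure, a set of candidate
#' mediators and one or more outcomes: instrument selection for the
#' exposure, harmonization, univariable estimators with the Egger
#' pleiotropy test and (when enough instruments) MR-PRESSO per
#' exposure-outcome pair; a univariable screen of the exposure on every
#' mediator (step 1); for mediators passing the configured screen, MR of
#' the mediator on each outcome using the mediator's own instruments
#' (step 2) and the two-step mediation decomposition against that
#' outcome's total effect; optional multivariable IVW adjusting the
#' exposure for co-exposures; and Bonferroni flags on every reported
#' p-value. Failures (e.g. an unreadable mediator file) are isolated per
#' pair: the run continues and the failure is recorded in the report.
#'
#' @param config named list with fields: `exposure` (path, data.frame or
#'   [SummaryStats-class]); `outcomes`, `mediators` (named lists of the
#'   same); `ld` (path or [LDMatrix-class]); `seed` (mandatory when any
#'   stochastic step runs); optional `coExposures` (named list, enables
#'   multivariable adjustment); thresholds `pInstrument` (5e-8), `r2`
#'   (0.001), `weakF` (10); estimator settings `ivwMode`, `nBoot` (1000),
#'   `pressoNSim` (5000, set 0 to skip PRESSO); `alpha` (0.05), `nTests`
#'   (defaults to the number of candidate mediators); `gate` ("nominal" or
#'   "bonferroni") and `gateAlpha` (0.05), the step-1 screen deciding which
#'   mediators enter mediation.
#' @return a [StudyReport-class]. Rerunning with an identical config (and
#'   seeds) reproduces it exactly.
#' @export
runStudy <- function(config) {
    cfg <- utils::modifyList(list(
        pInstrument = 5e-8, r2 = 0.001, weakF = 10,
        ivwMode = "default", nBoot = 1000L, pressoNSim = 5000L,
        alpha = 0.05, nTests = NULL, gate = "nominal", gateAlpha = 0.05,
        coExposures = NULL), config)
    for (f in c("exposure", "outcomes", "mediators", "ld"))
        if (is.null(cfg[[f]])) stop("config field '", f, "' is required")
    if (is.null(cfg$seed)) stop("config field 'seed' is required")
    if (is.null(cfg$nTests)) cfg$nTests <- max(1L, length(cfg$mediators))
    bonf <- bonferroniThreshold(cfg$alpha, cfg$nTests)
    gateP <- if (identical(cfg$gate, "bonferroni")) bonf else cfg$gateAlpha

    ld <- if (is.character(cfg$ld)) readLDMatrix(cfg$ld) else cfg$ld
    exposure <- .resolveStats(cfg$exposure, "exposure")

    failures <- data.frame(stage = character(0), pair = character(0),
                           message = character(0), stringsAsFactors = FALSE)
    fail <- function(stage, pair, e) {
        failures <<- rbind(failures, data.frame(
            stage = stage, pair = pair, message = conditionMessage(e),
            stringsAsFactors = FALSE))
        NULL
    }
    estRows <- list(); pressoRes <- list(); mvmrRes <- list()
    medRows <- list()

    sel <- selectInstruments(exposure, ld, pThreshold = cfg$pInstrument,
                             r2Threshold = cfg$r2,
                             weakFThreshold = cfg$weakF)
    expSel <- .subsetStats(exposure, sel@selectedIds)

    addEst <- function(pair, role, tab) {
        tab <- cbind(pair = pair, role = role, tab,
                     stringsAsFactors = FALSE)
        tab$sig_nominal <- tab$pval < cfg$alpha
        tab$sig_bonferroni <- tab$pval < bonf
        estRows[[length(estRows) + 1L]] <<- tab
    }

    # total effects: exposure -> each outcome
    totals <- list()
    outcomes <- list()
    for (onm in names(cfg$outcomes)) {
        pair <- paste0("exposure->", onm)
        res <- tryCatch({
            out <- .resolveStats(cfg$outcomes[[onm]], onm)
            h <- harmonize(expSel, out)
            addEst(pair, "total", mrAllMethods(h, seed = cfg$seed,
                                               nBoot = cfg$nBoot))
            totals[[onm]] <- mrIVW(h, mode = cfg$ivwMode)
            if (cfg$pressoNSim >= 1000L && length(h@snpIds) >= 4L)
                pressoRes[[pair]] <- mrPresso(h, nSim = cfg$pressoNSim,
                                              seed = cfg$seed)
            out
        }, error = function(e) fail("total", pair, e))
        outcomes[[onm]] <- res
    }

    # step 1 screen: exposure -> each mediator
    step1 <- list()
    mediators <- list()
    for (mnm in names(cfg$mediators)) {
        pair <- paste0("exposure->", mnm)
        tryCatch({
            med <- .resolveStats(cfg$mediators[[mnm]], mnm)
            h <- harmonize(expSel, med)
            addEst(pair, "step1", mrAllMethods(h, seed = cfg$seed,
                                               nBoot = cfg$nBoot))
            step1[[mnm]] <- mrIVW(h, mode = cfg$ivwMode)
            mediators[[mnm]] <- med
        }, error = function(e) fail("step1", pair, e))
    }

    # mediation: exactly the mediators whose step-1 p passes the gate
    passing <- names(step1)[vapply(step1, function(e) e@pval < gateP,
                                   logical(1))]
    for (mnm in passing) {
        med <- mediators[[mnm]]
        selM <- tryCatch(
            selectInstruments(med, ld, pThreshold = cfg$pInstrument,
                              r2Threshold = cfg$r2,
                              weakFThreshold = cfg$weakF),
            error = function(e) fail("select", mnm, e))
        if (is.null(selM)) next
        medSel <- .subsetStats(med, selM@selectedIds)
        for (onm in names(totals)) {
            if (is.null(totals[[onm]])) next
            pair <- paste0(mnm, "->", onm)
            tryCatch({
                h2 <- harmonize(medSel, outcomes[[onm]])
                addEst(pair, "step2", mrAllMethods(h2, seed = cfg$seed,
                                                   nBoot = cfg$nBoot))
                b <- mrIVW(h2, mode = cfg$ivwMode)
                mres <- twoStepMediation(step1[[mnm]], b, totals[[onm]])
                row <- cbind(mediator = mnm, outcome = onm,
                             as.data.frame(mres), stringsAsFactors = FALSE)
                medRows[[length(medRows) + 1L]] <- row
            }, error = function(e) fail("mediation", pair, e))
        }
    }

    # multivariable adjustment for co-exposures, one model per outcome
    if (!is.null(cfg$coExposures)) {
        coex <- lapply(cfg$coExposures, .resolveStats, what = "coExposure")
        allExp <- c(list(exposure = exposure), coex)
        pool <- unique(unlist(lapply(allExp, function(x) {
            tryCatch(selectInstruments(x, ld,
                         pThreshold = cfg$pInstrument,
                         r2Threshold = cfg$r2)@selectedIds,
                     error = function(e) character(0))
        })))
        for (onm in names(totals)) {
            if (is.null(outcomes[[onm]])) next
            pair <- paste0("mv:exposure->", onm)
            tryCatch({
                mv <- harmonizeMV(allExp, outcomes[[onm]], snpIds = pool)
                mvmrRes[[pair]] <- mvmrIVW(mv)
            }, error = function(e) fail("mvmr", pair, e))
        }
    }

    new("StudyReport",
        estimates = if (length(estRows) > 0L) do.call(rbind, estRows)
                    else data.frame(),
        presso = pressoRes, mvmr = mvmrRes,
        mediation = if (length(medRows) > 0L) do.call(rbind, medRows)
                    else data.frame(),
        failures = failures,
        provenance = list(
            seed = cfg$seed, p_instrument = cfg$pInstrument, r2 = cfg$r2,
            weak_f = cfg$weakF, ivw_mode = cfg$ivwMode, n_boot = cfg$nBoot,
            presso_n_sim = cfg$pressoNSim, alpha = cfg$alpha,
            n_tests = cfg$nTests, bonferroni_threshold = bonf,
            gate = cfg$gate, gate_p = gateP,
            n_instruments = length(sel@selectedIds),
            mean_f = sel@meanF, n_weak = sel@nWeakFlagged,
            mediators_passing_gate = passing))
}

#' Write a StudyReport to a directory
#'
#' Emits the estimates and mediation tables as TSV, per-pair MR-PRESSO
#' reports, MVMR tables, the failure log, and the provenance log as JSON.
#'
#' @param report a [StudyReport-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeStudyReport <- function(report, dir) {
    stopifnot(is(report, "StudyReport"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeResultsTable(report@estimates, file.path(dir, "estimates.tsv"))
    if (nrow(report@mediation) > 0L)
        writeMediationTable(report@mediation,
                            file.path(dir, "mediation.tsv"))
    for (nm in names(report@presso))
        writePressoReport(report@presso[[nm]],
            file.path(dir, paste0("presso_", gsub("[^A-Za-z0-9]", "_", nm),
                                  ".tsv")))
    for (nm in names(report@mvmr))
        writeResultsTable(as.data.frame(report@mvmr[[nm]]),
            file.path(dir, paste0("mvmr_", gsub("[^A-Za-z0-9]", "_", nm),
                                  ".tsv")))
    if (nrow(report@failures) > 0L)
        utils::write.table(report@failures, file.path(dir, "failures.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(report@provenance,
                         file.path(dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(dir)
}
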