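Package: exerkin
Title: Markerless Exergame Kinematics and Progression Biomarkers for
    Parkinson's Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for markerless exergame-based motor
    monitoring in Parkinson's disease. Reads 30-fps recordings of 33
    MediaPipe-style skeletal landmarks with game event logs, conditions
    the trajectories (median filter, cubic-spline resampling to 50 Hz,
    zero-phase low-pass Butterworth), extracts motor functional
    parameters (joint angles, range of motion, angular velocities,
    bilateral Symmetry Index) and game-based metrics, computes the
    Normalized Efficiency Index (NEI) summarizing progression through
    game difficulty levels, and assesses clinical validity against
    MDS-UPDRS Part III scores with Spearman rank correlations,
    independent t-tests, and questionnaire domain analysis. Includes a
    synthetic skeletal-trajectory and cohort simulator with known ground
    truth for end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
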