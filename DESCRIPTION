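Package: ernadose
Title: Individualised Tc-99m HSA Activity Planning for CZT SPECT
    Radionuclide Angiography
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Patient-tailored planning of administered Tc-99m human serum
    albumin activity for equilibrium radionuclide angiography on
    cadmium-zinc-telluride SPECT cameras. Combines two closed-form
    count-rate regressions on weight, height, sex, and age through a
    body-weight branch rule with minimum-dose floors, adjusts activities
    for the actual injection time by physical decay, predicts acquisition
    count rates, and converts activities to effective dose. Includes a
    synthetic-cohort simulator with group presets and calibrated
    multiplicative measurement noise, plus the audit statistics of a
    dosing protocol: measured-versus-predicted regression, per-group dose
    summaries, patient-flow accounting, reading averaging, a two-analyst
    ejection-fraction agreement rule, and paravenous-injection flagging.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
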