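Package: mealcount
Title: Hospital Calorie Counts: Intake Accounting, Quality Control, and
    Method-Agreement Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for multi-component hospital nutrient-intake assessment.
    Generates and edits per-tray Nutritional Intake Assessment Forms (NIAFs)
    from a menu cycle and food-composition database, converts recorded
    percent-consumed values and weighed-food records into served and consumed
    nutrient totals, and implements the quality-control rules used with
    photograph review (discrepancy flagging, rater proficiency, retraining
    trigger). Provides the statistical machinery for evaluating such a system:
    Bland-Altman limits of agreement, accuracy and intraclass-correlation
    mixed models fitted by REML, and a log-time mixed model estimating the
    time efficiency of one assessment method relative to another, together
    with a design-aware method-label resolver and a simulator of trays,
    consumption, rater error, and task times.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    lme4,
    lmerTest,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
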