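Package: lonelysense
Title: Passive-Sensing Behavioral Features and Detection of Loneliness in College Students
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying loneliness from passively sensed smartphone and
    wearable data streams. Provides a synthetic cohort generator emulating
    AWARE-style smartphone logs (location, Bluetooth, screen, calls, SMS,
    audio inferences) and Fitbit-style steps and sleep streams with planted,
    configurable links between behavior and loneliness; UCLA-20 loneliness
    scale scoring with level and change categorization; behavioral feature
    extraction over epoch-by-day-filter-by-granularity time segments
    (mobility and significant places via DBSCAN, campus-map categories,
    study and social duration, step bouts, sleep efficiency, communication,
    screen usage, Bluetooth device classification); nested randomized
    logistic regression feature selection; a leave-one-subject-out per-sensor
    ensemble classifier of loneliness level and change; and Apriori mining of
    behavior-loneliness association rules.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    glmnet,
    xgboost,
    geosphere,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
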