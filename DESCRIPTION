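Package: ventilab
Title: Ventilator-Patient Simulation, Iterative Learning PID Control, and
    Breath-Mode Classification Benchmarks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates a lumped first-order-plus-dead-time ventilator-patient
    model, closes the loop with PID and current-cycle-feedback iterative
    learning (ILC-PID) controllers for pressure (CPAP, PAV) and
    volume-controlled breathing, generates synthetic per-breath clinical
    feature tables, and benchmarks six classifier families on ventilation-mode
    prediction with grid search, 5-fold cross-validation, confusion-matrix
    metrics and ROC curves. Includes a rule-based neural classifier evaluator
    and a command-line interface for the simulate/dataset/bench/report
    workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    rpart,
    nnet,
    e1071,
    class,
    xgboost,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
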