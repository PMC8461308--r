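Package: tremorglove
Title: Quantifying and Predicting Electrical-Muscle-Stimulation Suppression
    of Parkinsonian Resting Tremor from Wrist Gyroscope Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing wrist-worn gyroscope recordings of
    parkinsonian resting tremor under electrical muscle stimulation (EMS).
    Provides a virtual-patient simulator reproducing the stepped 1 mA
    amplitude-ramp stimulation protocol, windowed root-mean-square feature
    extraction and dominant tremor-frequency estimation, tremor reset-time
    metrics, construction of labelled multiclass stimulation datasets with
    patient-wise grouped cross-validation, a suite of five stimulation-class
    predictors (multinomial logistic regression, random forest, support
    vector machine, multilayer perceptron, and LSTM) with teacher forcing,
    a simulated closed-loop stimulation controller, and the supporting
    statistics (Wilcoxon signed-rank, Spearman correlation, stepwise linear
    regression of tremor reset time).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    nnet,
    randomForest,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
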