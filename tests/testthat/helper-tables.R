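# Published regression fixture: 21 confusion matrices (7 classifiers x
# 3 channel subsets) with the metric values printed alongside them.
# Percentages carry 1 decimal, MCC 2-3 decimals; NA marks cells printed
# as "-" (no positive prediction).
published_metric_rows <- function() {
  read.csv(text = 'channels,algorithm,tn,fp,fn,tp,accuracy,mse,recall,precision,f1,specificity,mcc
16,naive_bayes,142,8,152,10,48.7,51.3,6.2,55.6,11.1,94.7,0.018
16,gradient_boosted_trees,125,25,28,134,83.0,17.0,82.7,84.3,83.5,83.3,0.66
16,support_vector,150,0,162,0,48.1,51.9,0,NA,NA,100,0
16,decision_tree,130,20,50,112,77.6,22.4,69.1,84.8,76.2,86.7,0.56
16,k_nearest_neighbor,91,59,70,92,58.7,41.3,56.8,60.9,58.8,60.7,0.175
16,logistic_regression,125,25,109,53,57.1,42.9,32.7,67.9,44.2,83.3,0.185
16,random_forest,133,17,81,81,68.6,31.4,50.0,82.7,62.3,88.7,0.416
13,naive_bayes,132,20,139,21,49.0,51.0,13.1,51.2,20.9,86.8,0
13,gradient_boosted_trees,131,21,29,131,84.0,16.0,81.9,86.2,84.0,86.2,0.681
13,support_vector,152,0,160,0,48.7,51.3,0,NA,NA,100,0
13,decision_tree,134,18,59,101,75.3,24.7,63.1,84.9,72.4,88.2,0.528
13,k_nearest_neighbor,92,60,74,86,57.1,42.9,53.8,58.9,56.2,60.5,0.143
13,logistic_regression,109,43,100,60,54.2,45.8,37.5,58.3,45.6,71.7,0.098
13,random_forest,137,15,71,89,72.4,27.6,55.6,85.6,67.4,90.1,0.485
8,naive_bayes,131,21,133,27,50.6,49.4,16.9,56.3,26.0,86.2,0.042
8,gradient_boosted_trees,124,28,28,132,82.1,17.9,82.5,82.5,82.5,81.6,0.641
8,support_vector,152,0,160,0,48.7,51.3,0,NA,NA,100,0
8,decision_tree,131,21,66,94,72.1,27.9,58.8,81.7,68.4,86.2,0.466
8,k_nearest_neighbor,92,60,66,94,59.6,40.4,58.8,61.0,59.9,60.5,0.193
8,logistic_regression,104,48,97,63,53.5,46.5,39.4,56.8,46.5,68.4,0.081
8,random_forest,138,14,66,94,74.4,25.6,58.8,87.0,70.1,90.8,0.520',
           stringsAsFactors = FALSE)
}

# Worked count-vectorizer example: three short texts over eight words.
worked_count_example <- function() {
  docs <- list(
    c("this", "study", "text", "example"),
    c("a", "source", "text", "example", "example", "vector"),
    c("a", "this", "study", "source", "text", "text", "time"))
  terms <- c("a", "this", "study", "source", "text", "example", "vector",
             "time")
  counts <- matrix(c(0, 1, 1, 0, 1, 1, 0, 0,
                     1, 0, 0, 1, 1, 2, 1, 0,
                     1, 1, 1, 1, 2, 0, 0, 1),
                   nrow = 3, byrow = TRUE, dimnames = list(NULL, terms))
  list(docs = docs, counts = counts)
}
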