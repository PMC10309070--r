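rank,description,auroc,auroc_lo,auroc_hi,ap,ap_lo,ap_hi,c_index,c_index_lo,c_index_hi
1,Deep multitask logistic regression using EMR features and tumor volume,0.823,0.777,0.866,0.505,0.420,0.602,0.801,0.757,0.842
2,Fuzzy logistic regression (binary) and Cox proportional hazards (risk) using EMR features and tumor volume,0.816,0.767,0.860,0.502,0.418,0.598,0.746,0.700,0.788
3,Fuzzy logistic regression (binary) or Cox proportional hazards (risk) using EMR features and engineered radiomic features,0.808,0.758,0.856,0.490,0.406,0.583,0.748,0.703,0.792
4,Multitask logistic regression using EMR features,0.798,0.748,0.845,0.429,0.356,0.530,0.785,0.740,0.827
5,3D convnet using cropped image patch with EMR features concatenated before binary classification layer,0.786,0.734,0.837,0.420,0.347,0.525,0.774,0.725,0.819
6,2D convnet using largest GTV image and contour slices with EMR features after nonlinear encoding,0.783,0.730,0.834,0.438,0.360,0.540,0.773,0.724,0.820
7,3D DenseNet using cropped image patch with EMR features concatenated before multitask prediction layer,0.780,0.733,0.824,0.353,0.290,0.440,0.781,0.740,0.819
8,Multilayer perceptron with SELU activation and binary output layer using EMR features,0.779,0.721,0.832,0.415,0.343,0.519,0.768,0.714,0.817
9,Two-stream 3D DenseNet with multitask prediction layer using tumor patch and downsampled context patch,0.766,0.718,0.811,0.311,0.260,0.391,0.748,0.703,0.790
10,2D convnet using largest GTV image and contour slices and binary output layer,0.735,0.677,0.792,0.357,0.289,0.455,0.722,0.667,0.774
11,3D convnet using cropped image patch and binary output layer,0.717,0.661,0.770,0.268,0.225,0.339,0.706,0.653,0.756
12,Fuzzy logistic regression (binary) and Cox proportional hazards (risk) using engineered radiomic features,0.716,0.655,0.772,0.341,0.272,0.433,0.695,0.638,0.749
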