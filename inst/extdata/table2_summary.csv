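# Printed rows of a published biologic-therapy responsiveness summary
# (n = 30 paired pre/post measurements; means, 95% CI of the mean change,
# and the printed standardized response mean). CI bounds are entered as
# ordered magnitudes; where the printed sign was typographically ambiguous
# the positive magnitude is used. For metrics that increase with treatment
# (PDFF, SPARCC SSS fat) the printed CI refers to the post-pre change, so
# reconstruction under the pre-post convention flags them as inconsistent.
metric,mean_pre,mean_post,ci_low,ci_high,printed_srm,printed_p
BASDAI,6.88,4.91,1.15,2.97,0.89,<0.001
Spinal VAS,6.90,4.76,1.19,3.07,0.85,<0.001
ASDAS CRP,3.32,2.40,0.53,1.32,0.88,<0.001
ASDAS ESR,3.19,2.29,0.56,1.24,0.98,<0.001
CRP,5.35,1.99,0.5798,6.134,0.45,0.020
SPARCC BME,15.18,10.60,1.317,7.850,0.52,0.008
SPARCC SSS (fat),17.73,19.63,0.7982,4.598,0.26,0.161
ADC mean,291.22,277.16,0.37,28.49,0.37,0.056
ADC median,195.21,170.52,5.83,43.53,0.50,0.012
ADC 25,8.59,4.09,1.87,10.83,0.27,0.159
ADC 75,476.4,457.2,2.35,40.62,0.34,0.078
ADC 90,585.3,573.9,8.56,46.31,0.26,0.170
PDFF mean,57.39,59.54,0.426,4.73,0.31,0.098
PDFF median,56.79,58.76,0.83,4.78,0.27,0.161
PDFF 25,47.84,50.26,0.73,5.57,0.29,0.127
PDFF 75,66.84,68.92,0.43,4.57,0.31,0.100
PDFF 90,51.21,50.53,0.54,3.90,0.28,0.132
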