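scenario,term,estimate,se
ovsynch,(Intercept),-0.5,0.0
ovsynch,submission_risk,2.4,0.0
ovsynch,submission_risk^2,-5.2,0.3
ovsynch,pregnancy_risk,0.5,0.1
ovsynch,pregnancy_risk^2,2.0,0.3
ovsynch,yield_305d,0.0,0.0
ovsynch,vwp,0.0,0.0
ovsynch,submission_risk:vwp,0.0,0.0
ovsynch,submission_risk^2:vwp,0.0,0.0
ovsynch,pregnancy_risk:vwp,0.0,0.0
ovsynch,pregnancy_risk^2:vwp,0.1,0.0
ovsynch,pregnancy_risk:submission_risk,4.59,0.2
ovsynch,pregnancy_risk:submission_risk^2,-19.5,1.6
ovsynch,herd_variance,0.3,0.0
ovsynch_p4,(Intercept),-0.5,0.0
ovsynch_p4,submission_risk,2.7,0.0
ovsynch_p4,submission_risk^2,-5.8,0.3
ovsynch_p4,pregnancy_risk,0.6,0.1
ovsynch_p4,pregnancy_risk^2,2.2,0.3
ovsynch_p4,yield_305d,0.0,0.0
ovsynch_p4,vwp,0.0,0.0
ovsynch_p4,submission_risk:vwp,0.0,0.0
ovsynch_p4,submission_risk^2:vwp,0.1,0.0
ovsynch_p4,pregnancy_risk:vwp,0.0,0.0
ovsynch_p4,pregnancy_risk^2:vwp,0.1,0.0
ovsynch_p4,pregnancy_risk:submission_risk,5.5,0.2
ovsynch_p4,pregnancy_risk:submission_risk^2,-21.1,1.6
ovsynch_p4,herd_variance,0.3,0.0
double_pg,(Intercept),-0.2,0.0
double_pg,submission_risk,0.3,0.0
double_pg,submission_risk^2,0.7,0.2
double_pg,pregnancy_risk,-0.2,0.0
double_pg,pregnancy_risk^2,0.8,0.2
double_pg,vwp,0.0,0.0
double_pg,pregnancy_risk:submission_risk,0.7,0.2
double_pg,herd_variance,0.2,0.0
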