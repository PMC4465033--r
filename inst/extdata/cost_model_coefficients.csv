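scenario,term,estimate,se
ovsynch,(Intercept),-64.7,0.6
ovsynch,submission_risk,134.3,2.0
ovsynch,submission_risk^2,-103.3,13.8
ovsynch,pregnancy_risk,-128.7,3.0
ovsynch,pregnancy_risk^2,112.3,13.9
ovsynch,yield_305d,-1.2,0.2
ovsynch,vwp,-1.9,0.1
ovsynch,cull_cost,-0.1,0.0
ovsynch,serve_cost,0.4,0.0
ovsynch,submission_risk:vwp,-3.1,0.2
ovsynch,submission_risk^2:vwp,4.6,1.2
ovsynch,pregnancy_risk:vwp,-3.9,0.2
ovsynch,pregnancy_risk^2:vwp,7.2,1.2
ovsynch,pregnancy_risk:submission_risk,404.4,12.4
ovsynch,pregnancy_risk:submission_risk^2,-810.3,88.5
ovsynch,herd_variance,976.8,13.8
ovsynch_p4,(Intercept),-78.0,0.6
ovsynch_p4,submission_risk,142.8,2.0
ovsynch_p4,submission_risk^2,-106.3,14.1
ovsynch_p4,pregnancy_risk,-155.5,3.0
ovsynch_p4,pregnancy_risk^2,120.0,14.2
ovsynch_p4,yield_305d,-1.4,0.2
ovsynch_p4,vwp,-1.9,0.1
ovsynch_p4,cull_cost,-0.1,0.0
ovsynch_p4,serve_cost,0.3,0.0
ovsynch_p4,submission_risk:vwp,-3.2,0.2
ovsynch_p4,submission_risk^2:vwp,4.7,1.2
ovsynch_p4,pregnancy_risk:vwp,-3.8,0.2
ovsynch_p4,pregnancy_risk^2:vwp,7.6,1.2
ovsynch_p4,pregnancy_risk:submission_risk,446.0,12.4
ovsynch_p4,pregnancy_risk:submission_risk^2,-825.2,88.5
ovsynch_p4,herd_variance,1023.3,14.5
double_pg,(Intercept),-5.5,0.4
double_pg,submission_risk,11.6,1.3
double_pg,submission_risk^2,44.5,9.0
double_pg,pregnancy_risk,-5.9,1.3
double_pg,pregnancy_risk^2,29.2,9.1
double_pg,vwp,0.0,0.0
double_pg,submission_risk:vwp,-0.4,0.1
double_pg,pregnancy_risk:vwp,-1.3,0.1
double_pg,pregnancy_risk^2:vwp,2.5,0.8
double_pg,pregnancy_risk:submission_risk,46.1,8.0
double_pg,herd_variance,420.9,6.0
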