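feature_set,model,split,t0p0,t0p1,t0p2,t1p0,t1p1,t1p2,t2p0,t2p1,t2p2,printed_total
full_spectra,plsda,calibration,539,0,0,0,601,1,0,0,481,99.94
full_spectra,plsda,validation,291,0,0,0,303,0,0,0,241,100
full_spectra,plsda,prediction,268,0,7,0,299,1,0,0,240,99.02
full_spectra,svm,calibration,539,0,0,0,602,0,0,0,481,100
full_spectra,svm,validation,289,0,2,0,303,0,0,0,241,99.76
full_spectra,svm,prediction,224,0,51,0,300,0,0,0,240,93.74
full_spectra,cnn,calibration,539,0,0,1,601,0,6,0,475,99.57
full_spectra,cnn,validation,289,0,2,0,303,0,4,0,237,99.28
full_spectra,cnn,prediction,253,0,22,0,300,0,0,0,240,97.30
effective_wavelengths,plsda,calibration,538,0,1,1,601,0,1,0,480,99.92
effective_wavelengths,plsda,validation,291,0,0,0,303,0,0,0,241,100
effective_wavelengths,plsda,prediction,272,0,3,0,300,0,0,0,240,99.63
effective_wavelengths,svm,calibration,539,0,0,0,602,0,2,0,479,99.88
effective_wavelengths,svm,validation,271,0,20,0,303,0,1,0,240,97.49
effective_wavelengths,svm,prediction,238,0,37,0,300,0,1,0,239,95.34
effective_wavelengths,cnn,calibration,539,0,0,0,602,0,4,0,477,99.75
effective_wavelengths,cnn,validation,287,0,4,0,303,0,8,0,233,98.56
effective_wavelengths,cnn,prediction,263,0,12,0,299,1,5,0,235,97.79
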