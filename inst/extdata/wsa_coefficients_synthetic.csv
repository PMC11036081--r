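category,input_dim,a,b
Bulk carriers,DWT,4.0,0.69
Cargo,DWT,5.0,0.67
Container,DWT,4.6,0.68
Tanker,DWT,4.2,0.70
Fishing vessels,DWT,8.0,0.63
Fishing vessels,BOA,6.0,2.00
Tugs and supply,DWT,9.0,0.62
Tugs and supply,BOA,5.5,2.00
Passenger ships,DWT,7.5,0.65
Passenger ships,BOA,6.5,2.00
Other,DWT,7.0,0.65
Other,LOA,0.9,1.45
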