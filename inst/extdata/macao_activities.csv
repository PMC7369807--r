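posture,activity,frequency
standing,watch,55
standing,taking pictures,307
standing,conversation,217
standing,waiting for the bus,312
standing,shopping,95
sitting,rest,261
sitting,conversation,28
sitting,sale of goods,16
exercise,running,5
relax,look around,11
relax,eat,15
relax,drink,21
rely_on,waiting for bus,32
rely_on,rest,68
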