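city,generalized,observed
Atlanta,83,105
Boston,149,83
Chicago,290,503
Dallas,86,17
Houston,32,35
Los Angeles,61,182
Miami,32,43
New York,507,368
Philadelphia,92,46
Washington D.C.,114,177
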