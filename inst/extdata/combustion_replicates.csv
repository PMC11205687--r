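"compound","massic_energy"
"furfurylamine",-29591.73
"furfurylamine",-29582.7
"furfurylamine",-29589.96
"furfurylamine",-29589.56
"furfurylamine",-29593.49
"furfurylamine",-29581.42
"5-methylfurfurylamine",-31577.92
"5-methylfurfurylamine",-31568.06
"5-methylfurfurylamine",-31562.26
"5-methylfurfurylamine",-31577.61
"5-methylfurfurylamine",-31586.75
"5-methylfurfurylamine",-31579.48
"5-methylfurfurylamine",-31589.8
"5-methylfurfurylamine",-31584.93
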