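>EGF4 start=139 synthetic
GSADCDERIMCSATLVCRIDGSATLVKCYCGSAYLVKRCM
>EGF5 start=180 synthetic
GSADCDERIMCSATLVCRIDGSATLVKCYCGSAHLVKRCM
>EGF6 start=221 synthetic
GSATCVKRIMCSATLVCRIMGSATLVKCICGSAYLVKRCM
>EGF7 start=262 synthetic
GSADCDDRIMCSATLVCRIDGSATLVKCYCGSAWLVKRCM
>EGF8 start=303 synthetic
GSADCDERIMCSATLVCRIDGSATLVKCYCGSAYLVKRCM
>EGF9 start=344 synthetic
GSADCDDRIMCSATLVCRIDGSATLVKCYCGSATLVKRCM
>EGF10 start=384 synthetic
GSATCVKRIMCSATLVCRIMGSATLVKCICGSAYLVKRCM
>EGF11 start=425 synthetic
GSADCDERIMCSATLVCRIDGSATLVKCYCGSAYLVKRCM
>EGF12 start=466 synthetic
GSADCDERIMCSATLVCRIDGSATLVKCYCGSAYLVKRCM
>EGF13 start=507 synthetic
GSADCDERIMCSATLVCRIDGSATLVKCYCGSAYLVKRCM
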