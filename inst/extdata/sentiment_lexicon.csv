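term,polarity
good,1
great,1
excellent,1
wonderful,1
hope,1
hopeful,1
grateful,1
thank,1
thanks,1
proud,1
success,1
successful,1
celebrate,1
happy,1
joy,1
encouraging,1
improving,1
improved,1
strong,1
stronger,1
safe,1
safely,1
win,1
winning,1
progress,1
milestone,1
congratulations,1
best,1
better,1
love,1
support,1
supportive,1
relief,1
recover,1
recovered,1
brave,1
heroes,1
inspiring,1
optimistic,1
confident,1
bad,-1
terrible,-1
awful,-1
crisis,-1
fear,-1
afraid,-1
sad,-1
tragic,-1
tragedy,-1
death,-1
deaths,-1
dying,-1
failure,-1
failed,-1
failing,-1
worst,-1
worse,-1
angry,-1
anger,-1
outbreak,-1
emergency,-1
danger,-1
dangerous,-1
threat,-1
warning,-1
panic,-1
shortage,-1
collapse,-1
devastating,-1
devastated,-1
loss,-1
losses,-1
grief,-1
mourning,-1
severe,-1
critical,-1
alarming,-1
suffering,-1
struggle,-1
struggling,-1
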