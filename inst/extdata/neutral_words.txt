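school
class
teacher
homework
computer
phone
game
games
video
music
song
movie
book
books
reading
writing
math
science
history
project
week
weekend
morning
evening
night
today
tomorrow
yesterday
time
year
month
people
friend
friends
family
parents
brother
sister
house
home
room
food
dinner
lunch
breakfast
pizza
water
coffee
walk
walking
running
sport
sports
soccer
basketball
internet
online
forum
thread
posting
posted
comment
question
answer
idea
thing
things
stuff
work
working
job
money
store
town
city
street
car
bus
train
weather
rain
snow
summer
winter
spring
autumn
news
update
message
chat
group
team
player
level
account
screen
keyboard
window
door
table
chair
paper
pen
picture
photo
camera
dog
cat
bird
tree
garden
park
lesson
exam
grade
college
club
guitar
piano
drawing
painting
episode
series
channel
playlist
headphones
backpack
notebook
pencil
calendar
schedule
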